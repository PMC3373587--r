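# Tabular output: tab-separated tables with full-precision floats and
# deterministic column order (the species order of the model).

fmt_num <- function(x) sprintf("%.17g", x)

#' Write an analysis result as a tab-separated table
#'
#' Steady-state results produce one row per selected species with columns
#' `species`, `RE`, `EMRE`, `SD`, `CV`.  Time courses produce one row per
#' time point with the RE means, LNA standard deviations, upper-triangle
#' covariances and EMRE means of the selected species.  Ensemble results
#' use the same layout as time courses plus `n_realizations` and `seed`
#' columns.  Floats are written in full precision so the table re-reads to
#' the original values.
#'
#' @param result An `sse_steady_state`, `sse_timecourse` or
#'   `ssa_ensemble`.
#' @param path Output path; `""` writes to standard output.
#' @param species Optional subset of species ids to report.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path, species = NULL) {
  tab <- result_table(result, species)
  lines <- c(paste(colnames(tab), collapse = "\t"),
             apply(tab, 1L, function(r) paste(r, collapse = "\t")))
  if (identical(path, "")) writeLines(lines) else writeLines(lines, path)
  invisible(path)
}

select_species <- function(all_ids, species) {
  if (is.null(species)) return(all_ids)
  bad <- setdiff(species, all_ids)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  all_ids[all_ids %in% species]    # keep model order
}

result_table <- function(result, species = NULL) {
  if (inherits(result, "sse_steady_state")) {
    ids <- select_species(result$species, species)
    i <- match(ids, result$species)
    cbind(species = ids,
          RE = fmt_num(result$phi_ss[i]),
          EMRE = fmt_num(as.numeric(result$emre_ss)[i]),
          SD = fmt_num(result$sd[i]),
          CV = fmt_num(result$cv[i]))
  } else if (inherits(result, "sse_timecourse")) {
    ids <- select_species(result$species, species)
    i <- match(ids, result$species)
    out <- cbind(time = fmt_num(result$t))
    for (k in seq_along(ids))
      out <- cbind(out, stats::setNames(list(fmt_num(result$phi[, i[k]])),
                                        paste0(ids[k], "_RE"))[[1]])
    colnames(out) <- c("time", paste0(ids, "_RE"))
    if (!is.null(result$sd)) {
      sd <- result$sd[, i, drop = FALSE]; colnames(sd) <- paste0(ids, "_SD")
      out <- cbind(out, apply(sd, 2L, fmt_num))
      for (a in seq_along(ids)) for (b in a:length(ids)) {
        cn <- paste0("cov_", ids[a], "_", ids[b])
        out <- cbind(out, fmt_num(result$cov[, i[a], i[b]]))
        colnames(out)[ncol(out)] <- cn
      }
    }
    if (!is.null(result$emre_mean)) {
      em <- result$emre_mean[, i, drop = FALSE]
      colnames(em) <- paste0(ids, "_EMRE")
      out <- cbind(out, apply(em, 2L, fmt_num))
    }
    out
  } else if (inherits(result, "ssa_ensemble")) {
    ids <- select_species(result$species, species)
    i <- match(ids, result$species)
    out <- cbind(time = fmt_num(result$t))
    mm <- result$mean[, i, drop = FALSE]; colnames(mm) <- paste0(ids, "_mean")
    sd <- result$sd[, i, drop = FALSE]; colnames(sd) <- paste0(ids, "_SD")
    out <- cbind(out, apply(mm, 2L, fmt_num), apply(sd, 2L, fmt_num))
    for (a in seq_along(ids)) for (b in a:length(ids)) {
      cn <- paste0("cov_", ids[a], "_", ids[b])
      out <- cbind(out, fmt_num(result$cov[, i[a], i[b]]))
      colnames(out)[ncol(out)] <- cn
    }
    out <- cbind(out, n_realizations = as.character(result$n_realizations),
                 seed = as.character(result$seed))
    out
  } else stop("no table writer for class ", class(result)[1])
}

#' Plot an SSE time course
#'
#' RE mean concentrations with an LNA standard-deviation band (when
#' available) and EMRE means (dashed).
#'
#' @param x An `sse_timecourse`.
#' @param species Optional subset of species ids.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sse_timecourse <- function(x, species = NULL, ...) {
  ids <- select_species(x$species, species)
  i <- match(ids, x$species)
  graphics::matplot(x$t, x$phi[, i, drop = FALSE], type = "l", lty = 1,
                    xlab = sprintf("time"), ylab = "concentration", ...)
  if (!is.null(x$sd)) {
    for (k in seq_along(i)) {
      graphics::lines(x$t, x$phi[, i[k]] + x$sd[, i[k]], lty = 3, col = k)
      graphics::lines(x$t, x$phi[, i[k]] - x$sd[, i[k]], lty = 3, col = k)
    }
  }
  if (!is.null(x$emre_mean))
    graphics::matlines(x$t, x$emre_mean[, i, drop = FALSE], lty = 2)
  graphics::legend("topright", legend = ids, col = seq_along(i), lty = 1,
                   bty = "n")
  invisible(x)
}
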