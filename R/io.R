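#' Read a long-format expression CSV
#'
#' Schema: columns \code{time_h, gene, replicate, condition, value};
#' comment lines prefixed \code{#}. A missing column raises an error
#' naming it.
#'
#' @param path file path.
#' @return data.frame of class \code{expression_series}.
#' @export
read_expression_csv <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("time_h", "gene", "replicate", "condition", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("expression CSV schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  class(tab) <- c("expression_series", class(tab))
  tab
}

#' Write a long-format expression CSV
#'
#' @param series \code{expression_series} (or compatible data.frame).
#' @param path output path.
#' @param comment optional comment line(s) written with a \code{#}
#'   prefix.
#' @export
write_expression_csv <- function(series, path, comment = NULL) {
  need <- c("time_h", "gene", "replicate", "condition", "value")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("expression series missing column(s) ",
         paste(miss, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(as.data.frame(series)[need], con, row.names = FALSE)
  invisible(path)
}

#' Read / write the gas-exchange CSV
#'
#' Schema: \code{time_h, condition, parameter, replicate, value, units}.
#' @param path file path.
#' @return data.frame.
#' @export
read_gas_exchange_csv <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("time_h", "condition", "parameter", "replicate", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("gas-exchange CSV schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  tab
}

#' @rdname read_gas_exchange_csv
#' @param tab gas-exchange table.
#' @param comment optional comment line(s).
#' @export
write_gas_exchange_csv <- function(tab, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Rhythm table for an expression series or trajectory
#'
#' Mirrors the period/phase summary layout used for reporting: one row
#' per gene x condition with mean and standard deviation of period and
#' phase. Sparse replicate series are analysed per replicate with the
#' harmonic fit and aggregated across replicates; dense simulated series
#' (a \code{clock_trajectory}) are analysed once per method (harmonic
#' fit, MESA, Enright) and aggregated across methods.
#'
#' @param x an \code{expression_series} data.frame or a
#'   \code{clock_trajectory}.
#' @param genes genes to analyse (default: all present / the six clock
#'   genes).
#' @param period_window searched period range (h).
#' @return data.frame with columns \code{gene}, \code{condition},
#'   \code{period}, \code{period_sd}, \code{phase}, \code{phase_sd},
#'   \code{n}.
#' @export
rhythm_table <- function(x, genes = NULL, period_window = c(18, 34)) {
  if (inherits(x, "clock_trajectory")) {
    genes <- genes %||% c("CL", "P97", "P51", "EL", "GI", "RVE8")
    cond <- if (!is.null(x$treatment))
      sprintf("I=%g", x$treatment$intensity) else "sim"
    rows <- lapply(genes, function(g) {
      s <- trajectory_series(x, .gene_mrna[[g]])
      res <- estimate_rhythm(s$time_h, s$value, period_window)
      # phase: the dominant peak of the first treatment cycle (ZT h)
      data.frame(gene = g, condition = cond,
                 period = res$summary$period_mean,
                 period_sd = res$summary$period_sd,
                 phase = .phase_peak(s$time_h, s$value,
                                     res$summary$period_mean),
                 phase_sd = res$summary$phase_sd,
                 n = res$summary$n)
    })
    return(do.call(rbind, rows))
  }
  stopifnot(is.data.frame(x))
  genes <- genes %||% unique(x$gene)
  rows <- list()
  for (cond in unique(x$condition)) {
    for (g in intersect(genes, unique(x$gene))) {
      sub <- x[x$gene == g & x$condition == cond, ]
      ests <- lapply(sort(unique(sub$replicate)), function(r) {
        sr <- sub[sub$replicate == r, ]
        sr <- sr[order(sr$time_h), ]
        est <- estimate_mfourfit(sr$time_h, sr$value, period_window)
        ph <- .phase_peak(sr$time_h, sr$value, est$period)
        if (!is.na(ph)) est$phase <- ph
        est
      })
      agg <- aggregate_estimates(ests)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond,
        period = agg$period_mean, period_sd = agg$period_sd,
        phase = agg$phase_mean, phase_sd = agg$phase_sd, n = agg$n)
    }
  }
  do.call(rbind, rows)
}
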