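# shared binning and formatting helpers

#' Bin definitions used for promiscuity degrees and publication counts
#'
#' Both the promiscuity-degree distribution and the per-compound
#' publication-frequency distribution are reported over the same eight
#' intervals: 1, 2, 3, 4, 5, 6-10, 11-20 and >20.
#'
#' @return A list with `labels` (character), `lower` and `upper` (integer
#'   bounds of each bin, the last bin open-ended in use but capped at 80 by
#'   the synthetic generator).
#' @export
promiscuity_bins <- function() {
  list(
    labels = c("1", "2", "3", "4", "5", "6-10", "11-20", ">20"),
    lower  = c(1L, 2L, 3L, 4L, 5L, 6L, 11L, 21L),
    upper  = c(1L, 2L, 3L, 4L, 5L, 10L, 20L, 80L)
  )
}

# cut positive integer counts into the shared 8-bin scheme
bin_factor <- function(x) {
  stopifnot(all(x >= 1))
  cut(x,
    breaks = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 10.5, 20.5, Inf),
    labels = promiscuity_bins()$labels
  )
}

#' Format a percentage the way the summary tables print it
#'
#' One decimal place, except values below 0.1 percent which are given two
#' decimals so that rare bins do not print as "0.0".
#'
#' @param pct Numeric vector of percentages (0-100 scale).
#' @return Character vector.
#' @export
format_percent <- function(pct) {
  ifelse(pct < 0.1, sprintf("%.2f", pct), sprintf("%.1f", pct))
}

# shortest decimal string that parses back to exactly the same double;
# used when numbers are embedded in joined text fields, where the writer
# cannot rely on the CSV serialiser's round-trip guarantee
fmt_num <- function(x) {
  out <- character(length(x))
  done <- !is.finite(x)
  out[done] <- as.character(x[done])
  for (d in 1:17) {
    if (all(done)) break
    s <- formatC(x[!done], digits = d, format = "g", width = 1)
    ok <- suppressWarnings(as.numeric(s)) == x[!done]
    ok[is.na(ok)] <- FALSE
    idx <- which(!done)
    out[idx[ok]] <- s[ok]
    done[idx[ok]] <- TRUE
  }
  out
}

# locale-independent row ordering for deterministic file output
radix_order <- function(df, cols) {
  do.call(order, c(unname(as.list(df[cols])), list(method = "radix")))
}
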