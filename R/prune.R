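#' Prune correlated variants
#'
#' Greedily removes one member of each variant pair whose squared LD
#' correlation meets the threshold until no such pair remains. From each
#' offending pair the variant with the *larger* exposure p-value is
#' dropped (i.e. the more strongly associated variant is kept); ties are
#' broken by genomic position order (the earlier variant is kept). When
#' several pairs tie at the maximum r-squared the first pair in storage
#' order is resolved first, so the result is deterministic.
#'
#' @param data a [harmonized_data] object.
#' @param r2_threshold squared-correlation threshold in (0, 1]; pairs with
#'   `rho^2 >= r2_threshold` are broken up. Default 0.4.
#' @param exposure exposure column whose p-values drive the keep rule;
#'   `NULL` (default) uses each variant's smallest p-value across
#'   exposures.
#' @return The pruned [harmonized_data]; removed variant ids are recorded
#'   in `attr(, "removed")`.
#' @export
prune_correlated <- function(data, r2_threshold = 0.4, exposure = NULL) {
  stopifnot(inherits(data, "harmonized_data"),
            r2_threshold > 0, r2_threshold <= 1)
  z <- abs(data$bx) / data$sx
  pmat <- 2 * pnorm(-z)
  pval <- if (is.null(exposure)) apply(pmat, 1L, min) else pmat[, exposure]
  keep <- seq_along(data$variants)
  removed <- character(0L)
  repeat {
    r2 <- data$rho[keep, keep, drop = FALSE]^2
    r2[lower.tri(r2, diag = TRUE)] <- 0   # work on the upper triangle only
    m <- max(r2)
    if (m < r2_threshold || length(keep) < 2L) break
    ij <- which(r2 == m, arr.ind = TRUE)
    ij <- ij[order(ij[, 1L], ij[, 2L])[1L], ]
    a <- keep[ij[1L]]; b <- keep[ij[2L]]
    drop_idx <- if (pval[a] > pval[b]) a
      else if (pval[b] > pval[a]) b
      else if (data$positions[a] <= data$positions[b]) b else a
    removed <- c(removed, data$variants[drop_idx])
    keep <- setdiff(keep, drop_idx)
  }
  out <- subset_variants(data, keep)
  attr(out, "removed") <- removed
  out
}
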