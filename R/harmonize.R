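#' Harmonized two-sample MR input
#'
#' Container aligning per-variant exposure associations (SD units, one
#' column per exposure), outcome associations (log-odds) and a signed LD
#' correlation matrix to a common effect allele per variant.
#'
#' @param bx matrix (variants x exposures) of per-allele exposure effects in
#'   SD units; a vector is treated as one column.
#' @param sx matching standard errors.
#' @param by,sy per-allele log-odds outcome effects and standard errors.
#' @param rho signed LD correlation matrix of effect-allele dosages;
#'   identity when `NULL`.
#' @param variants variant identifiers.
#' @param exposures,outcome trait labels.
#' @param positions optional genomic order used for deterministic
#'   tie-breaking when pruning.
#' @return An object of class `harmonized_data`.
#' @export
harmonized_data <- function(bx, sx, by, sy, rho = NULL, variants = NULL,
                            exposures = NULL, outcome = "outcome",
                            positions = NULL) {
  bx <- as.matrix(bx); sx <- as.matrix(sx)
  J <- nrow(bx); K <- ncol(bx)
  if (!all(dim(sx) == dim(bx))) stop("bx and sx dimensions differ")
  if (length(by) != J || length(sy) != J)
    stop("outcome series length does not match number of variants")
  if (any(sy <= 0) || any(sx <= 0)) stop("all standard errors must be > 0")
  if (is.null(rho)) rho <- diag(J)
  rho <- as.matrix(rho)
  if (!all(dim(rho) == c(J, J))) stop("LD matrix dimension mismatch")
  if (max(abs(rho - t(rho))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(rho) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("LD matrix is not positive semi-definite")
  variants <- variants %||% rownames(bx) %||% sprintf("var_%03d", seq_len(J))
  exposures <- exposures %||% colnames(bx) %||% sprintf("exposure_%d", seq_len(K))
  dimnames(bx) <- dimnames(sx) <- list(variants, exposures)
  dimnames(rho) <- list(variants, variants)
  structure(list(bx = bx, sx = sx, by = as.numeric(by), sy = as.numeric(sy),
                 rho = rho, variants = variants, exposures = exposures,
                 outcome = outcome,
                 positions = positions %||% seq_len(J)),
            class = "harmonized_data")
}

#' @export
print.harmonized_data <- function(x, ...) {
  cat(sprintf("Harmonized MR data: %d variants, %d exposure(s) [%s] -> %s\n",
              length(x$variants), length(x$exposures),
              paste(x$exposures, collapse = ", "), x$outcome))
  invisible(x)
}

#' Subset harmonized data by variant index
#' @param data a [harmonized_data] object.
#' @param idx integer or logical index over variants.
#' @export
subset_variants <- function(data, idx) {
  harmonized_data(data$bx[idx, , drop = FALSE], data$sx[idx, , drop = FALSE],
                  data$by[idx], data$sy[idx],
                  data$rho[idx, idx, drop = FALSE],
                  variants = data$variants[idx], exposures = data$exposures,
                  outcome = data$outcome, positions = data$positions[idx])
}

allele_complement <- function(a) {
  chartr("ACGTacgt", "TGCAtgca", a)
}

is_palindromic <- function(ea, oa) allele_complement(ea) == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome associations to the exposure effect alleles, flipping the
#' outcome beta sign and allele frequency where the allele coding is
#' reversed. Strand flips are recognised by allele complement. Palindromic
#' variants (A/T or C/G pairs) are resolved by allele frequency when both
#' frequencies are far from 0.5 (`|eaf - 0.5| > freq_window`) and dropped
#' otherwise; set `palindromic = "drop"` to always drop them or `"keep"` to
#' assume both files are on the same strand.
#'
#' @param exposure summary-statistics data.frame (see
#'   [read_summary_stats()]) holding one or more exposure traits.
#' @param outcome summary-statistics data.frame for a single outcome trait.
#' @param ld optional signed LD matrix with variant ids as dimnames, aligned
#'   to the exposure effect alleles; subset and reordered to the harmonized
#'   variant set.
#' @param exposures traits to extract from `exposure` (default: all, in
#'   first-appearance order).
#' @param palindromic policy for palindromic variants.
#' @param freq_window frequency window around 0.5 within which palindromic
#'   variants are considered unresolvable.
#' @return A [harmonized_data] object. Variants missing from either side or
#'   with irreconcilable alleles are dropped with a message.
#' @export
harmonize <- function(exposure, outcome, ld = NULL, exposures = NULL,
                      palindromic = c("freq", "drop", "keep"),
                      freq_window = 0.08) {
  palindromic <- match.arg(palindromic)
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  if (length(unique(outcome$trait)) != 1L)
    stop("outcome must contain a single trait")
  exposures <- exposures %||% unique(exposure$trait)
  exp_split <- lapply(exposures, function(tr) {
    d <- exposure[exposure$trait == tr, , drop = FALSE]
    if (nrow(d) == 0L) stop("exposure trait not found: ", tr)
    d[!duplicated(d$variant_id), , drop = FALSE]
  })
  names(exp_split) <- exposures

  ids <- Reduce(intersect, c(lapply(exp_split, `[[`, "variant_id"),
                             list(outcome$variant_id)))
  if (length(ids) == 0L) stop("no variants shared between exposure and outcome")

  ref <- exp_split[[1L]][match(ids, exp_split[[1L]]$variant_id), ]
  out <- outcome[match(ids, outcome$variant_id), ]

  align_one <- function(d, ref) {
    # returns +1 (aligned), -1 (flip), NA (drop)
    ea <- toupper(d$effect_allele); oa <- toupper(d$other_allele)
    rea <- toupper(ref$effect_allele); roa <- toupper(ref$other_allele)
    flip <- rep(NA_real_, nrow(d))
    pal <- is_palindromic(rea, roa)
    same <- ea == rea & oa == roa
    swap <- ea == roa & oa == rea
    cmp_same <- allele_complement(ea) == rea & allele_complement(oa) == roa
    cmp_swap <- allele_complement(ea) == roa & allele_complement(oa) == rea
    flip[(same | cmp_same) & !pal] <- 1
    flip[(swap | cmp_swap) & !pal] <- -1
    if (any(pal)) {
      if (palindromic == "keep") {
        flip[pal & same] <- 1; flip[pal & swap] <- -1
      } else if (palindromic == "freq") {
        resolvable <- pal & abs(d$eaf - 0.5) > freq_window &
          abs(ref$eaf - 0.5) > freq_window
        agree <- (d$eaf > 0.5) == (ref$eaf > 0.5)
        flip[pal] <- NA
        flip[resolvable & (same | cmp_same) & agree] <- 1
        flip[resolvable & (same | cmp_same) & !agree] <- -1
        flip[resolvable & (swap | cmp_swap) & !agree] <- -1
        flip[resolvable & (swap | cmp_swap) & agree] <- 1
      } # "drop": leave NA
    }
    flip
  }

  flip_out <- align_one(out, ref)
  flips_exp <- lapply(exp_split, function(d)
    align_one(d[match(ids, d$variant_id), ], ref))
  keep <- !is.na(flip_out) & Reduce(`&`, lapply(flips_exp, function(f) !is.na(f)))
  if (!any(keep)) stop("no variants could be harmonized")
  if (any(!keep))
    message("dropping ", sum(!keep), " variant(s) during harmonization: ",
            paste(head(ids[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "")

  ids <- ids[keep]; ref <- ref[keep, ]; out <- out[keep, ]
  flip_out <- flip_out[keep]

  bx <- sapply(seq_along(exposures), function(k) {
    d <- exp_split[[k]][match(ids, exp_split[[k]]$variant_id), ]
    d$beta * flips_exp[[k]][keep]
  })
  sx <- sapply(seq_along(exposures), function(k) {
    exp_split[[k]][match(ids, exp_split[[k]]$variant_id), "se"]
  })
  bx <- matrix(bx, ncol = length(exposures))
  sx <- matrix(sx, ncol = length(exposures))
  colnames(bx) <- colnames(sx) <- exposures

  rho <- NULL
  if (!is.null(ld)) {
    if (is.null(rownames(ld))) stop("LD matrix needs variant ids as dimnames")
    miss <- setdiff(ids, rownames(ld))
    if (length(miss) > 0L)
      stop("variants missing from LD matrix: ", paste(miss, collapse = ", "))
    rho <- ld[ids, ids, drop = FALSE]
  }
  harmonized_data(bx, sx, out$beta * flip_out, out$se, rho,
                  variants = ids, exposures = exposures,
                  outcome = out$trait[1L],
                  positions = ref$pos %||% seq_along(ids))
}
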