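#' Drug-target gene region specification
#'
#' A gene region used as a pharmacological proxy: HMGCR (statins), PCSK9
#' (PCSK9 inhibitors), LDLR, NPC1L1 (ezetimibe), APOC3 and LPL
#' (triglyceride-lowering targets). Estimates for HMGCR, PCSK9, LDLR and
#' NPC1L1 are scaled per SD of LDL-cholesterol; APOC3 and LPL per SD of
#' triglycerides. Region variants must be pairwise not strongly correlated
#' (r-squared below `r2_threshold`) against the supplied LD matrix.
#'
#' @param gene one of HMGCR, PCSK9, LDLR, NPC1L1, APOC3, LPL.
#' @param variants variant id vector.
#' @param scaling_trait `"LDL"` or `"TG"`; defaults to (and is validated
#'   against) the gene's canonical scaling trait.
#' @param variance_explained declared fraction of the scaling trait's
#'   variance explained by the region variants.
#' @param ld optional signed LD matrix used to validate the r-squared
#'   rule at construction.
#' @param r2_threshold pairwise squared-correlation ceiling (default 0.4).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(gene, variants, scaling_trait = NULL,
                        variance_explained = NA_real_, ld = NULL,
                        r2_threshold = 0.4) {
  canon <- c(HMGCR = "LDL", PCSK9 = "LDL", LDLR = "LDL", NPC1L1 = "LDL",
             APOC3 = "TG", LPL = "TG")
  if (!gene %in% names(canon))
    stop("unknown gene region: ", gene)
  if (is.null(scaling_trait)) scaling_trait <- canon[[gene]]
  if (scaling_trait != canon[[gene]])
    stop(gene, " estimates are scaled per SD of ", canon[[gene]],
         ", not ", scaling_trait)
  stopifnot(length(variants) >= 1L, !anyDuplicated(variants))
  if (!is.null(ld)) {
    miss <- setdiff(variants, rownames(ld))
    if (length(miss) > 0L)
      stop("region variants missing from LD matrix: ",
           paste(miss, collapse = ", "))
    r2 <- ld[variants, variants, drop = FALSE]^2
    diag(r2) <- 0
    if (max(r2) >= r2_threshold) {
      ij <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
      stop(sprintf("region %s violates the r2 < %.2g rule: %s, %s (r2 = %.3f)",
                   gene, r2_threshold, variants[ij[1L]], variants[ij[2L]],
                   max(r2)))
    }
  }
  structure(list(gene = gene, variants = variants,
                 scaling_trait = scaling_trait,
                 variance_explained = variance_explained,
                 r2_threshold = r2_threshold),
            class = "region_spec")
}

#' Gene-region registry
#'
#' The shipped registry of drug-target regions with their scaling traits
#' and declared variance explained in the scaling trait (editable config;
#' variant id lists are study-specific and are supplied per analysis).
#'
#' @return data.frame with columns `gene`, `scaling_trait`,
#'   `variance_explained` (fraction of the scaling trait) and
#'   `variance_explained_ldl`.
#' @export
gene_region_registry <- function() {
  path <- system.file("extdata", "gene_regions.tsv", package = "lipidmr")
  read.delim(path, stringsAsFactors = FALSE)
}
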