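#' Zygosity of a diploid genotype call
#'
#' Classifies `a/b` (or phased `a|b`) genotype strings: both alleles the
#' same alternate -> homozygous; reference plus one alternate ->
#' heterozygous with reference; two distinct alternates -> heterozygous
#' without reference. Reference calls (`0/0`) and missing calls (`./.`)
#' carry no variant and return `NA`. Ploidy other than 2 is rejected.
#'
#' @param gt Character vector of genotype strings.
#' @return Character vector in `{"homozygous", "het_with_ref",
#'   "het_without_ref"}` or `NA`.
#' @export
classify_zygosity <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_character_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2) {
      stop("malformed or non-diploid genotype: '", g, "'")
    }
    if (any(alleles == ".")) return(NA_character_)
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a) || any(a < 0)) {
      stop("malformed genotype: '", g, "'")
    }
    if (all(a == 0)) return(NA_character_)
    if (a[1] == a[2]) return("homozygous")
    if (any(a == 0)) return("het_with_ref")
    "het_without_ref"
  }, character(1), USE.NAMES = FALSE)
}

# VEP-style consequence -> impact tier lookup.
.impact_table <- c(
  transcript_ablation = "HIGH", splice_acceptor_variant = "HIGH",
  splice_donor_variant = "HIGH", stop_gained = "HIGH",
  frameshift_variant = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  missense_variant = "MODERATE", inframe_insertion = "MODERATE",
  inframe_deletion = "MODERATE", protein_altering_variant = "MODERATE",
  synonymous_variant = "LOW", splice_region_variant = "LOW",
  stop_retained_variant = "LOW", start_retained_variant = "LOW",
  incomplete_terminal_codon_variant = "LOW",
  intron_variant = "MODIFIER", `5_prime_UTR_variant` = "MODIFIER",
  `3_prime_UTR_variant` = "MODIFIER", upstream_gene_variant = "MODIFIER",
  downstream_gene_variant = "MODIFIER", intergenic_variant = "MODIFIER",
  non_coding_transcript_exon_variant = "MODIFIER",
  non_coding_transcript_variant = "MODIFIER"
)

.tier_levels <- c("MODIFIER", "LOW", "MODERATE", "HIGH")

#' Predicted impact tier of a consequence term
#'
#' Maps VEP-style consequence vocabulary to the four impact tiers:
#' synonymous -> LOW, missense / in-frame indels -> MODERATE, frameshift /
#' stop-gain / splice donor-acceptor -> HIGH, non-coding (intronic, UTR,
#' up/downstream, intergenic) -> MODIFIER.
#'
#' @param consequence Character vector of consequence terms.
#' @param unknown `"error"` (default) rejects unknown terms; `"modifier"`
#'   maps them to MODIFIER with a warning.
#' @return Character vector of tiers.
#' @export
impact_tier <- function(consequence, unknown = c("error", "modifier")) {
  unknown <- match.arg(unknown)
  tier <- unname(.impact_table[consequence])
  if (anyNA(tier)) {
    bad <- unique(consequence[is.na(tier)])
    if (unknown == "error") {
      stop("unknown consequence term(s): ", paste(bad, collapse = ", "))
    }
    warning("unknown consequence term(s) mapped to MODIFIER: ",
            paste(bad, collapse = ", "))
    tier[is.na(tier)] <- "MODIFIER"
  }
  tier
}

#' Classify variant records by zygosity and impact
#'
#' Joins genotype calls with per-(variant, gene) consequence annotations.
#' When a variant has several consequence terms for one gene, the most
#' severe tier wins (HIGH > MODERATE > LOW > MODIFIER). Records without an
#' alternate allele (reference or missing genotypes) are dropped.
#'
#' @param vcf Data frame with columns `ID` and a genotype column (named
#'   `sample` or given via `gt_col`), e.g. from [read_vcf()].
#' @param consequences Data frame: `variant_id`, `gene`, `consequence`.
#' @param gt_col Name of the genotype column (default `"sample"`).
#' @param unknown Passed to [impact_tier()].
#' @return Data frame, one row per (variant, gene): variant_id, gene,
#'   zygosity, consequence (the most severe term), tier.
#' @export
classify_variants <- function(vcf, consequences, gt_col = "sample",
                              unknown = "error") {
  if (!all(c("ID", gt_col) %in% names(vcf))) {
    stop("VCF table needs columns ID and ", gt_col)
  }
  gt <- vcf[[gt_col]]
  # strip FORMAT extras: GT is the first colon-separated field
  gt <- sub(":.*$", "", gt)
  zyg <- stats::setNames(classify_zygosity(gt), vcf$ID)
  cons <- consequences[consequences$variant_id %in% vcf$ID, , drop = FALSE]
  cons$tier <- impact_tier(cons$consequence, unknown = unknown)
  cons$zygosity <- unname(zyg[cons$variant_id])
  cons <- cons[!is.na(cons$zygosity), , drop = FALSE]
  # most severe tier per (variant, gene)
  sev <- match(cons$tier, .tier_levels)
  ord <- order(cons$variant_id, cons$gene, -sev)
  cons <- cons[ord, , drop = FALSE]
  cons <- cons[!duplicated(cons[, c("variant_id", "gene")]), , drop = FALSE]
  rownames(cons) <- NULL
  cons[, c("variant_id", "gene", "zygosity", "consequence", "tier")]
}

#' Summarize classified variants
#'
#' Contingency counts of zygosity x impact tier over (variant, gene) rows,
#' plus the distinct-variant count (which the row count can exceed when
#' variants annotate multiple genes) and per-consequence counts within
#' each tier.
#'
#' @param classified Output of [classify_variants()].
#' @return List: `by_class` (3 x 4 zygosity x tier count matrix),
#'   `n_variants` (distinct variants), `n_rows` ((variant, gene) rows),
#'   `by_consequence` (data frame tier, consequence, count).
#' @export
summarize_variants <- function(classified) {
  zyg_levels <- c("homozygous", "het_with_ref", "het_without_ref")
  tab <- table(factor(classified$zygosity, levels = zyg_levels),
               factor(classified$tier, levels = .tier_levels))
  if (nrow(classified)) {
    bc <- as.data.frame(table(tier = classified$tier,
                              consequence = classified$consequence),
                        stringsAsFactors = FALSE)
    bc <- bc[bc$Freq > 0, , drop = FALSE]
    names(bc)[3] <- "count"
    rownames(bc) <- NULL
  } else {
    bc <- data.frame(tier = character(), consequence = character(),
                     count = integer())
  }
  list(by_class = unclass(as.matrix(tab)),
       n_variants = length(unique(classified$variant_id)),
       n_rows = nrow(classified),
       by_consequence = bc)
}
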