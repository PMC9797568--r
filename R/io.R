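#' @name readers
#' @title Readers and writers for the pipeline file dialects
#' @description Plain-text dialects used throughout: edge TSV
#'   (`gene_a`, `gene_b`, `ppi_score` — STRING-style `protein1`,
#'   `protein2`, `combined_score` headers accepted), DEG TSV (`gene`,
#'   `log2FC`, `PValue`, `FDR`), phenotype CSV (one row per sample),
#'   expression TSV (genes x samples, first column `gene`), GMT (term,
#'   description, genes...), consequence TSV (`variant_id`, `gene`,
#'   `consequence`), and minimal VCF v4 with a GT FORMAT field. Every
#'   writer's output is readable by its reader without information loss.
NULL

.check_cols <- function(tab, req, path) {
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("file ", path, " missing column(s): ", paste(miss, collapse = ", "))
  }
  tab
}

#' Read a protein-interaction edge table
#' @param path TSV with columns `gene_a`, `gene_b`, `ppi_score` (or the
#'   STRING-style aliases `protein1`, `protein2`, `combined_score`).
#' @return Data frame with canonical column names.
#' @rdname readers
#' @export
read_edges <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  aliases <- c(gene_a = "protein1", gene_b = "protein2",
               ppi_score = "combined_score")
  for (canon in names(aliases)) {
    if (!canon %in% names(tab) && aliases[[canon]] %in% names(tab)) {
      names(tab)[names(tab) == aliases[[canon]]] <- canon
    }
  }
  .check_cols(tab, c("gene_a", "gene_b", "ppi_score"), path)
}

#' @rdname readers
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#' @rdname readers
#' @export
read_degs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_cols(tab, c("gene", "log2FC", "FDR"), path)
}

#' @rdname readers
#' @export
write_degs <- function(degs, path) {
  utils::write.table(degs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#' @rdname readers
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    if (length(parts) < 3) {
      stop("file ", path, ": GMT line with fewer than 3 fields: ",
           substr(l, 1, 40))
    }
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  sets
}

#' @rdname readers
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(tn) {
    paste(c(tn, tn, terms[[tn]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table (samples x phenotypes CSV)
#' @rdname readers
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(tab, "sample", path)
}

#' @rdname readers
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression matrix (TSV, first column `gene`)
#' @rdname readers
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  .check_cols(tab, "gene", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  m
}

#' @rdname readers
#' @export
write_expression <- function(expression, path) {
  tab <- data.frame(gene = rownames(expression), expression,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-(variant, gene) consequence annotations
#' @rdname readers
#' @export
read_consequences <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_cols(tab, c("variant_id", "gene", "consequence"), path)
}

#' @rdname readers
#' @export
write_consequences <- function(consequences, path) {
  utils::write.table(consequences, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a VCF with genotype calls
#'
#' Uses \pkg{vcfR}; returns the fixed columns plus the first sample's
#' genotype string in a `sample` column (positions stay 1-based).
#' @rdname readers
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix$POS <- as.integer(fix$POS)
  fix$sample <- unname(gt[, 1])
  fix
}

#' @rdname readers
#' @export
write_vcf <- function(vcf, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "sample"), collapse = "\t")
  )
  body <- apply(vcf[, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", "sample")],
                1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
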