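#' Sturges' rule bin count
#'
#' k = ceiling(1 + log2(n)).
#'
#' @param n Number of observations (>= 1).
#' @return Integer bin count.
#' @export
sturges_k <- function(n) {
  if (n < 1) stop("n must be >= 1")
  as.integer(ceiling(1 + log2(n)))
}

#' Equal-width discretization into k classes
#'
#' Bins span the observed range; the maximum falls in the top bin;
#' constant input maps everything to class 0. Labels are 0..k-1.
#'
#' @param values Numeric vector.
#' @param k Number of bins (default from [sturges_k()]).
#' @return Integer vector of class labels in 0..k-1.
#' @export
discretize <- function(values, k = sturges_k(length(values))) {
  stopifnot(length(values) >= 1, k >= 1)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0L, length(values)))
  lab <- floor((values - rng[1]) / (rng[2] - rng[1]) * k)
  as.integer(pmin(lab, k - 1))
}

# Log marginal likelihood of counts under a symmetric Dirichlet prior
# with total pseudo-count (equivalent sample size) a0 spread over the
# cells: Dirichlet-multinomial evidence.
.log_ml_dirichlet <- function(counts, a0) {
  k <- length(counts)
  a <- a0 / k
  lgamma(a0) - lgamma(a0 + sum(counts)) +
    sum(lgamma(a + counts) - lgamma(a))
}

#' Bayesian association between one gene's expression and a phenotype
#'
#' Both variables are discretized (equal-width Sturges bins); the score is
#' the log marginal likelihood of the phenotype classes given the gene
#' classes (Dirichlet-multinomial evidence per conditioning class, BDeu
#' prior with equivalent sample size `ess`) minus the evidence of the
#' phenotype classes alone. Positive scores mean conditioning on the gene
#' improves the evidence despite the extra parameters. The association
#' sign comes from the Pearson correlation of the undiscretized values.
#'
#' @param expr Numeric vector: one gene's expression across samples.
#' @param pheno Numeric vector: phenotype across the same samples (>= 4).
#' @param k Bin count (default Sturges from the sample count).
#' @param ess Equivalent sample size of the Dirichlet prior (default 1).
#' @param threshold Score needed to accept the association (default 0).
#' @return List: `bayes_score`, `passes`, `sign` (`"+"`/`"-"`, only when
#'   passing), `flag` (e.g. "zero_variance_phenotype").
#' @export
associate <- function(expr, pheno, k = sturges_k(length(expr)),
                      ess = 1, threshold = 0) {
  if (length(expr) != length(pheno)) stop("unequal sample counts")
  if (length(expr) < 4) stop("need at least 4 samples")
  if (stats::sd(pheno) == 0) {
    return(list(bayes_score = NA_real_, passes = FALSE, sign = NA_character_,
                flag = "zero_variance_phenotype"))
  }
  g <- discretize(expr, k)
  p <- discretize(pheno, k)
  lm0 <- .log_ml_dirichlet(tabulate(p + 1L, nbins = k), ess)
  g_classes <- sort(unique(g))
  lm1 <- sum(vapply(g_classes, function(gc) {
    .log_ml_dirichlet(tabulate(p[g == gc] + 1L, nbins = k),
                      ess / length(g_classes))
  }, numeric(1)))
  score <- lm1 - lm0
  passes <- score > threshold
  sgn <- if (passes) {
    if (stats::cor(expr, pheno) >= 0) "+" else "-"
  } else {
    NA_character_
  }
  list(bayes_score = score, passes = passes, sign = sgn, flag = NA_character_)
}

#' Associate every gene with every phenotype
#'
#' Applies [associate()] across an expression matrix and a phenotype
#' table.
#'
#' @param expression Genes x samples numeric matrix.
#' @param phenotypes Data frame with a `sample` column matching the matrix
#'   columns and one numeric column per phenotype (non-numeric columns
#'   such as `condition` are ignored).
#' @param ess,threshold Passed to [associate()].
#' @return Data frame: gene, phenotype, bayes_score, passes, sign.
#' @export
associate_all <- function(expression, phenotypes, ess = 1, threshold = 0) {
  if (!"sample" %in% names(phenotypes)) {
    stop("phenotype table needs a 'sample' column")
  }
  ord <- match(colnames(expression), phenotypes$sample)
  if (anyNA(ord)) stop("expression columns missing from phenotype table")
  ph_cols <- names(phenotypes)[vapply(phenotypes, is.numeric, TRUE)]
  rows <- list()
  for (ph in ph_cols) {
    y <- phenotypes[[ph]][ord]
    for (g in rownames(expression)) {
      a <- associate(expression[g, ], y, ess = ess, threshold = threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, phenotype = ph, bayes_score = a$bayes_score,
        passes = a$passes, sign = a$sign, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
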