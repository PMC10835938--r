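#' Additive-dosage association scan
#'
#' Per-variant linear regression of a log-transformed endpoint on allele
#' dosage (0-2) with optional fixed covariates: the additive-coding model
#' standard in genome-wide association analysis. Covariates are projected
#' out of both the endpoint and every dosage column once
#' (Frisch-Waugh-Lovell), so each per-variant fit is an exact least-squares
#' fit of the full model at a fraction of the cost; Wald t p-values use
#' n - k - 2 residual degrees of freedom (k covariates). Missing dosages are
#' imputed to the variant mean before regression; monomorphic (or
#' all-missing) variants are skipped with a reason.
#'
#' @param dosages Numeric matrix, subjects in rows, variants in columns
#'   (values in \[0, 2\]; `NA` allowed). Column names identify variants.
#' @param y Numeric endpoint (typically log concentration or log ratio).
#' @param covariates Optional data frame or matrix of covariates (no
#'   intercept column; one is always included). Rank-deficient covariate
#'   sets are an error.
#' @param variant_info Optional data frame with columns `id`, `chr`, `pos`
#'   (1-based) matched to the dosage columns by `id`.
#' @param sig_threshold Genome-wide significance level, default `5e-8`.
#' @return Object of class `assoc_scan`: data frame with `id`, `chr`, `pos`,
#'   `beta`, `se`, `p_value`, `neg_log10_p`, `significant`, `skipped`,
#'   `reason` (one row per variant).
#' @export
association_scan <- function(dosages, y, covariates = NULL,
                             variant_info = NULL, sig_threshold = 5e-8) {
  G <- as.matrix(dosages)
  if (is.null(colnames(G))) colnames(G) <- paste0("var_", seq_len(ncol(G)))
  n <- nrow(G)
  stopifnot(length(y) == n, all(is.finite(y)))
  rng <- range(G, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 2)
    stop("dosages must lie in [0, 2]")

  # mean-impute missing dosages per variant
  all_missing <- colSums(!is.na(G)) == 0L
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    mu[all_missing] <- 0  # placeholder; these variants are skipped below
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2L]]
  }

  # design: intercept + covariates, projected out of y and G
  X <- matrix(1, n, 1L)
  k <- 0L
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    storage.mode(C) <- "double"
    k <- ncol(C)
    X <- cbind(X, C)
    if (qr(X)$rank < ncol(X))
      stop("covariates are rank deficient")
  }
  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  RG <- qr.resid(qrX, G)

  sxx <- colSums(RG^2)
  mono <- all_missing | apply(G, 2L, function(g) length(unique(g)) < 2L)
  sxy <- colSums(RG * ry)
  beta <- sxy / sxx
  df <- n - k - 2L
  rss <- sum(ry^2) - beta * sxy        # residual SS of the full per-variant fit
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = df)

  skip <- mono | !is.finite(beta)
  beta[skip] <- NA_real_; se[skip] <- NA_real_; p[skip] <- NA_real_
  reason <- rep(NA_character_, ncol(G))
  reason[all_missing] <- "all dosages missing"
  reason[mono & !all_missing] <- "monomorphic"

  out <- data.frame(id = colnames(G), chr = NA_character_, pos = NA_integer_,
                    beta = beta, se = se, p_value = p,
                    neg_log10_p = -log10(p),
                    significant = !is.na(p) & p < sig_threshold,
                    skipped = skip, reason = reason,
                    stringsAsFactors = FALSE)
  if (!is.null(variant_info)) {
    i <- match(out$id, variant_info$id)
    out$chr <- as.character(variant_info$chr)[i]
    out$pos <- variant_info$pos[i]
  }
  rownames(out) <- NULL
  structure(out, class = c("assoc_scan", "data.frame"),
            sig_threshold = sig_threshold, n = n, covariates = k)
}

#' @export
print.assoc_scan <- function(x, n = 10L, ...) {
  cat(sprintf("Association scan: %d variants, %d subjects, %d covariate(s)\n",
              nrow(x), attr(x, "n"), attr(x, "covariates")))
  cat(sprintf("  genome-wide significant (p < %g): %d | skipped: %d\n\n",
              attr(x, "sig_threshold"), sum(x$significant), sum(x$skipped)))
  df <- as.data.frame(x)[order(as.data.frame(x)$p_value), ]
  print.data.frame(utils::head(df, n), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Linkage disequilibrium as squared dosage correlation
#'
#' @param a,b Numeric dosage vectors of equal length, both polymorphic.
#' @return Squared Pearson correlation in \[0, 1\].
#' @examples
#' ld_r2(c(0, 1, 2, 1), c(2, 1, 0, 1))  # 1: allele flip is sign-free
#' @export
ld_r2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("LD r2 is undefined for monomorphic variants")
  stats::cor(a, b)^2
}

#' Conditional re-scan adjusting for a lead variant
#'
#' Repeats the association scan with the named variant's dosage added to the
#' fixed covariates - the standard check for whether remaining signals are
#' independent or mere linkage-disequilibrium shadows of the lead hit. The
#' adjusting variant itself is skipped in the re-scan.
#'
#' @inheritParams association_scan
#' @param adjust_for Column name of the variant to condition on; must be
#'   polymorphic.
#' @return An `assoc_scan` for all other variants.
#' @export
conditional_scan <- function(dosages, y, covariates = NULL, adjust_for,
                             variant_info = NULL, sig_threshold = 5e-8) {
  G <- as.matrix(dosages)
  if (is.null(colnames(G))) colnames(G) <- paste0("var_", seq_len(ncol(G)))
  if (!adjust_for %in% colnames(G))
    stop("adjust_for variant '", adjust_for, "' not found in dosage matrix")
  g0 <- G[, adjust_for]
  if (anyNA(g0)) g0[is.na(g0)] <- mean(g0, na.rm = TRUE)
  if (stats::var(g0) == 0)
    stop("cannot adjust for a monomorphic variant")
  cov2 <- if (is.null(covariates)) data.frame(.lead = g0)
          else cbind(as.data.frame(covariates), .lead = g0)
  association_scan(G[, colnames(G) != adjust_for, drop = FALSE], y,
                   covariates = cov2, variant_info = variant_info,
                   sig_threshold = sig_threshold)
}

#' Read a dosage matrix from a VCF file
#'
#' Minimal genotype-only interface: the GT field of each sample is converted
#' to an ALT-allele dosage (0, 1, 2; missing calls to `NA`). Requires the
#' `vcfR` package.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return List with `dosages` (subjects x variants matrix) and
#'   `variant_info` (data frame `id`, `chr`, `pos`).
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_dosages requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(s) {
    if (is.na(s)) return(NA_real_)
    alleles <- strsplit(s, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  dos <- apply(gt, c(1L, 2L), count_alt)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  id <- ifelse(is.na(fix$ID) | fix$ID == ".",
               paste0(fix$CHROM, ":", fix$POS), fix$ID)
  rownames(dos) <- id
  list(dosages = t(dos),
       variant_info = data.frame(id = id, chr = fix$CHROM,
                                 pos = as.integer(fix$POS),
                                 stringsAsFactors = FALSE))
}

#' Manhattan-plot export table
#'
#' @param scan An `assoc_scan`.
#' @return Data frame `chr`, `pos`, `neg_log10_p` for plotting.
#' @export
manhattan_data <- function(scan) {
  stopifnot(inherits(scan, "assoc_scan"))
  df <- as.data.frame(scan)
  df[!df$skipped, c("chr", "pos", "neg_log10_p")]
}
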