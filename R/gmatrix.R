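#' SNP quality control for a -1/0/+1 genotype matrix
#'
#' Removes markers with call rate below \code{call_rate_min}, minor allele
#' frequency strictly below \code{maf_min}, or no chromosome assignment, in
#' that order of reporting (a marker failing several rules is counted under
#' each). Allele frequencies are allele-count based, so heterozygous calls
#' (code 0, rare in DH lines) contribute one copy of each allele. Surviving
#' markers are re-oriented so that -1 is the minor allele after filtering.
#'
#' @param markers a \code{marker_matrix} (see [simulate_dh_families()] or
#'   [read_genotypes()]).
#' @param call_rate_min minimum fraction of non-missing calls per marker.
#' @param maf_min markers with MAF strictly below this are removed; a marker
#'   at exactly the threshold is retained.
#' @return The filtered \code{marker_matrix} with \code{qc_state =
#'   "filtered"} and a \code{qc_report} attribute: counts removed per rule
#'   and the removed marker ids.
#' @export
qc_filter <- function(markers, call_rate_min = 0.95, maf_min = 0.05) {
  X <- markers$geno
  map <- markers$map
  call_rate <- colMeans(!is.na(X))
  n_pos <- colSums(X == 1L, na.rm = TRUE)
  n_het <- colSums(X == 0L, na.rm = TRUE)
  n_ok <- colSums(!is.na(X))
  p_plus <- ifelse(n_ok > 0, (2 * n_pos + n_het) / (2 * n_ok), NA_real_)
  maf <- pmin(p_plus, 1 - p_plus)
  unmapped <- is.na(map$chrom[match(colnames(X), map$marker)])

  fail_cr <- call_rate < call_rate_min
  fail_maf <- !is.na(maf) & maf < maf_min
  fail_maf[is.na(maf)] <- TRUE   # no calls at all
  keep <- !fail_cr & !fail_maf & !unmapped
  report <- list(
    n_input = ncol(X),
    n_call_rate = sum(fail_cr),
    n_maf = sum(fail_maf),
    n_unmapped = sum(unmapped),
    n_removed = sum(!keep),
    removed = colnames(X)[!keep]
  )
  if (!any(keep)) {
    stop(sprintf(
      "all %d markers removed by QC (call rate: %d, MAF: %d, unmapped: %d)",
      report$n_input, report$n_call_rate, report$n_maf, report$n_unmapped
    ))
  }
  X <- X[, keep, drop = FALSE]
  # re-orient so -1 is the minor allele (frequencies can flip after
  # subsetting lines, so this is recomputed here)
  flip <- p_plus[keep] < 0.5
  X[, flip] <- -X[, flip, drop = FALSE]
  out <- structure(list(
    geno = X,
    map = map[match(colnames(X), map$marker), , drop = FALSE],
    family = markers$family,
    qc_state = "filtered"
  ), class = "marker_matrix")
  attr(out, "qc_report") <- report
  out
}

#' Realized additive relationship matrix (VanRaden method 1)
#'
#' Missing codes are mean-imputed per marker; each marker is centered by
#' \code{2(p - 0.5)} where p is the +1-allele frequency; and
#' \code{K = W W' / (2 * sum(p (1 - p)))}. For fully inbred material the mean
#' diagonal is near 2 (= 1 + f with f = 1). If the smallest eigenvalue is
#' negative a fixed diagonal jitter of 1e-6 is added so downstream samplers
#' can factorize K; the jitter actually applied is recorded.
#'
#' @param markers a \code{marker_matrix}, normally after [qc_filter()] (a raw
#'   matrix is accepted with a warning).
#' @return An n x n \code{kinship_matrix} (a plain matrix with line ids as
#'   dimnames and a \code{jitter} attribute).
#' @export
additive_relationship <- function(markers) {
  if (!identical(markers$qc_state, "filtered"))
    warning("computing relationship matrix from non-QC'd markers")
  X <- markers$geno
  cm <- colMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    miss <- which(is.na(X), arr.ind = TRUE)
    X[miss] <- cm[miss[, 2L]]
  }
  p <- (colMeans(X) + 1) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers; cannot compute relationships")
  W <- sweep(X[, poly, drop = FALSE], 2L, 2 * (p[poly] - 0.5))
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(W) / denom
  jitter <- 0
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0) {
    jitter <- 1e-6
    diag(K) <- diag(K) + jitter
  }
  structure(K, class = c("kinship_matrix", "matrix"), jitter = jitter)
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d lines, mean diagonal %.3f, jitter %g\n",
              nrow(x), mean(diag(x)), attr(x, "jitter")))
  invisible(x)
}

#' Read a HapMap-format genotype file into the internal -1/0/+1 coding
#'
#' Standard HapMap text layout: 11 annotation columns (rs#, alleles, chrom,
#' pos, strand, assembly#, center, protLSID, assayLSID, panelLSID, QCcode)
#' followed by one column per sample holding two-letter diploid calls (e.g.
#' \code{AA}, \code{AC}); \code{NN} or \code{--} is missing. The major
#' homozygote is coded +1, the minor homozygote -1 and heterozygotes 0.
#'
#' @param path file path (tab- or whitespace-delimited).
#' @return a raw \code{marker_matrix}.
#' @export
read_hapmap <- function(path) {
  hm <- utils::read.table(path, header = TRUE, sep = "", as.is = TRUE,
                          check.names = FALSE, comment.char = "")
  meta <- hm[, 1:11]
  calls <- as.matrix(hm[, -(1:11), drop = FALSE])
  m <- nrow(hm)
  samples <- colnames(calls)
  geno <- matrix(NA_integer_, length(samples), m,
                 dimnames = list(samples, meta[[1L]]))
  for (j in seq_len(m)) {
    g <- toupper(calls[j, ])
    g[g %in% c("NN", "--", "N")] <- NA
    al <- sort(table(unlist(strsplit(stats::na.omit(g), ""))), decreasing = TRUE)
    if (length(al) == 0L) next
    major <- names(al)[1L]
    code <- ifelse(is.na(g), NA_integer_,
                   vapply(strsplit(g, ""), function(a) {
                     sum(a == major) - 1L
                   }, integer(1L)))
    geno[, j] <- code
  }
  map <- data.frame(marker = meta[[1L]],
                    chrom = suppressWarnings(as.integer(meta[[3L]])),
                    pos_cM = suppressWarnings(as.numeric(meta[[4L]])))
  rownames(map) <- map$marker
  structure(list(geno = geno, map = map,
                 family = NULL, qc_state = "raw"),
            class = "marker_matrix")
}
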