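# Plain-CSV interchange: genotypes + map, plot tables, BLUE tables, kinship.

#' Write genotypes and map to CSV
#'
#' Genotypes go to \code{<prefix>_geno.csv} (rows = lines, columns =
#' markers, codes -1/0/+1, empty cell = missing) and the map to
#' \code{<prefix>_map.csv} (marker, chrom, pos_cM).
#'
#' @param markers a \code{marker_matrix}.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_genotypes <- function(markers, prefix) {
  gf <- paste0(prefix, "_geno.csv")
  mf <- paste0(prefix, "_map.csv")
  g <- as.data.frame(markers$geno)
  utils::write.csv(cbind(line_id = rownames(markers$geno), g), gf,
                   row.names = FALSE, na = "")
  utils::write.csv(markers$map, mf, row.names = FALSE)
  invisible(c(geno = gf, map = mf))
}

#' Read genotypes and map from CSV
#'
#' Inverse of [write_genotypes()].
#'
#' @param prefix path prefix used when writing.
#' @return a raw \code{marker_matrix}.
#' @export
read_genotypes <- function(prefix) {
  g <- utils::read.csv(paste0(prefix, "_geno.csv"), check.names = FALSE)
  map <- utils::read.csv(paste0(prefix, "_map.csv"))
  geno <- as.matrix(g[, -1L, drop = FALSE])
  storage.mode(geno) <- "integer"
  rownames(geno) <- g[[1L]]
  rownames(map) <- map$marker
  structure(list(geno = geno, map = map, family = NULL, qc_state = "raw"),
            class = "marker_matrix")
}

#' Write / read a tidy plot table
#' @param plots a \code{plot_table}.
#' @param path CSV path.
#' @export
write_plot_table <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_plot_table
#' @export
read_plot_table <- function(path) {
  d <- utils::read.csv(path)
  need <- c("line_id", "environment", "block", "trait", "value")
  if (!all(need %in% names(d)))
    stop("plot table must have columns: ", paste(need, collapse = ", "))
  class(d) <- c("plot_table", "data.frame")
  d
}

#' Write / read a BLUE table
#' @param blues a \code{blue_table}.
#' @param path CSV path.
#' @export
write_blues <- function(blues, path) {
  utils::write.csv(blues, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blues
#' @export
read_blues <- function(path) {
  d <- utils::read.csv(path)
  need <- c("line_id", "trait", "scope", "blue")
  if (!all(need %in% names(d)))
    stop("BLUE table must have columns: ", paste(need, collapse = ", "))
  if (!"se" %in% names(d)) d$se <- NA_real_
  class(d) <- c("blue_table", "data.frame")
  d
}

#' Write / read a kinship matrix (line ids as header row and first column)
#' @param K a \code{kinship_matrix}.
#' @param path CSV path.
#' @export
write_kinship <- function(K, path) {
  utils::write.csv(data.frame(line_id = rownames(K), as.data.frame(unclass(K)),
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  K <- as.matrix(d[, -1L, drop = FALSE])
  rownames(K) <- d[[1L]]
  structure(K, class = c("kinship_matrix", "matrix"), jitter = 0)
}
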