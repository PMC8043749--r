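#' Genotype matrix container
#'
#' Allele-dosage genotypes for a strain panel: individuals in rows, SNPs in
#' columns, coded 0/1/2 copies of the minor-ish allele with `NA` for missing.
#' Dosage 1 arises for F1 hybrids whose genomes are deduced as parental
#' midpoints. Per-SNP metadata (`id`, `chrom`, `bp`) rides along in `map`.
#'
#' @param X numeric matrix (individuals x SNPs), values in \{0, 1, 2, NA\}.
#' @param map data frame with columns `id`, `chrom`, `bp`, one row per SNP.
#' @param ids optional individual identifiers (default rownames or 1..n).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(X, map, ids = NULL) {
  X <- as.matrix(X)
  .assert(ncol(X) == nrow(map), "map must have one row per SNP column")
  .assert(all(c("id", "chrom", "bp") %in% names(map)),
          "map needs columns id, chrom, bp")
  .assert(all(X %in% c(0, 1, 2) | is.na(X)), "dosages must be 0/1/2 or NA")
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  rownames(X) <- ids
  colnames(X) <- map$id
  structure(list(X = X, map = as.data.frame(map), ids = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs, %d chromosome(s)\n",
              nrow(x$X), ncol(x$X), length(unique(x$map$chrom))))
  invisible(x)
}

#' Per-SNP minor allele frequency and missing rate
#'
#' @param G a [genotype_matrix].
#' @return Data frame with `id`, `maf`, `missing`.
#' @export
snp_stats <- function(G) {
  p <- colMeans(G$X, na.rm = TRUE) / 2
  data.frame(id = G$map$id,
             maf = pmin(p, 1 - p),
             missing = colMeans(is.na(G$X)))
}

#' Filter SNPs on minor allele frequency and missingness
#'
#' Keeps SNPs with MAF at least `maf_min` and missing rate at most `miss_max`
#' (both inclusive), then mean-imputes the remaining missing dosages per SNP.
#'
#' @param G a [genotype_matrix].
#' @param maf_min MAF lower bound (default 0.10).
#' @param miss_max missing-rate upper bound (default 0.05).
#' @return A filtered, imputed [genotype_matrix].
#' @export
filter_genotypes <- function(G, maf_min = 0.10, miss_max = 0.05) {
  st <- snp_stats(G)
  keep <- st$maf >= maf_min - 1e-12 & st$missing <= miss_max + 1e-12
  if (!any(keep)) warning("no SNPs pass the filters")
  X <- G$X[, keep, drop = FALSE]
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  out <- list(X = X, map = G$map[keep, , drop = FALSE], ids = G$ids)
  class(out) <- "genotype_matrix"
  out
}

#' Read genotypes from PLINK text .ped/.map files
#'
#' Biallelic loci only. The dosage counts copies of the allele that is minor
#' in the sample (ties: the alphabetically first allele). `0` or `-9`
#' alleles are treated as missing.
#'
#' @param ped,map paths to the .ped and .map files.
#' @return A [genotype_matrix].
#' @export
read_plink <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  names(mp)[1:4] <- c("chrom", "id", "cm", "bp")[seq_len(min(4, ncol(mp)))]
  pd <- utils::read.table(ped, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  m <- nrow(mp)
  .assert(ncol(pd) == 6 + 2 * m, ".ped column count does not match .map")
  ids <- pd[[2]]
  a1 <- as.matrix(pd[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(pd[, 6 + 2 * seq_len(m), drop = FALSE])
  miss_code <- c("0", "-9", "N")
  X <- matrix(NA_real_, nrow(pd), m)
  for (j in seq_len(m)) {
    v1 <- a1[, j]; v2 <- a2[, j]
    ok <- !(v1 %in% miss_code) & !(v2 %in% miss_code)
    alleles <- sort(unique(c(v1[ok], v2[ok])))
    .assert(length(alleles) <= 2, sprintf("locus %s is not biallelic", mp$id[j]))
    if (length(alleles) == 0) next
    cnt <- table(factor(c(v1[ok], v2[ok]), levels = alleles))
    minor <- alleles[which.min(cnt)]          # first on ties
    X[ok, j] <- (v1[ok] == minor) + (v2[ok] == minor)
  }
  genotype_matrix(X, data.frame(id = mp$id, chrom = mp$chrom, bp = mp$bp),
                  ids = ids)
}

#' Write genotypes to PLINK text .ped/.map files
#'
#' Dosages are emitted as A/B allele pairs (dosage = copies of B); missing as
#' 0 0. Dosage 1 (F1 midpoint) becomes the heterozygote A B.
#'
#' @param G a [genotype_matrix] with integer dosages.
#' @param ped,map output paths.
#' @export
write_plink <- function(G, ped, map) {
  mp <- data.frame(G$map$chrom, G$map$id, 0, G$map$bp)
  utils::write.table(mp, map, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  X <- G$X
  lines <- vapply(seq_len(nrow(X)), function(i) {
    g <- X[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, "B", "A"))
    a2 <- ifelse(is.na(g), "0", ifelse(g >= 2, "B", "A"))
    paste(c("FAM", G$ids[i], "0", "0", "0", "-9", rbind(a1, a2)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, ped)
}

#' Read/write the simple CSV genotype dialect
#'
#' Rows are individuals (first column `id`), remaining columns are SNPs with
#' headers `chrom:bp:snpid`; cells are dosages 0/1/2 or empty for missing.
#'
#' @param path file path.
#' @return A [genotype_matrix].
#' @export
read_genotype_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  X <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  parts <- strsplit(colnames(X), ":", fixed = TRUE)
  map <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    bp = as.numeric(vapply(parts, `[`, "", 2)),
                    id = vapply(parts, `[`, "", 3))
  genotype_matrix(X, map[, c("id", "chrom", "bp")], ids = ids)
}

#' @rdname read_genotype_csv
#' @param G a [genotype_matrix].
#' @export
write_genotype_csv <- function(G, path) {
  hdr <- paste(G$map$chrom, G$map$bp, G$map$id, sep = ":")
  d <- data.frame(id = G$ids, G$X, check.names = FALSE)
  names(d) <- c("id", hdr)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}
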