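#' Construct a genotype matrix
#'
#' Container for unphased diploid calls at mapped SNPs: marker metadata
#' (id, linkage group, bp), a markers x individuals character matrix of
#' `"A/G"`-style calls (`NA` = missing), and the ids of the two parents.
#'
#' @param markers data frame with columns `marker`, `lg`, `bp`; `bp` must
#'   be strictly increasing within each linkage group.
#' @param geno character matrix, rows matching `markers$marker`, columns
#'   named by individual; entries like `"A/G"` (alleles sorted) or `NA`.
#' @param mother,father column names of the two parents.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(markers, geno, mother, father) {
  stopifnot(is.data.frame(markers),
            all(c("marker", "lg", "bp") %in% names(markers)),
            is.matrix(geno), nrow(geno) == nrow(markers))
  if (anyDuplicated(colnames(geno))) stop("duplicate individual ids")
  if (!all(c(mother, father) %in% colnames(geno))) {
    stop("mother and father must be columns of the genotype matrix")
  }
  ok <- tapply(markers$bp, markers$lg, function(x) all(diff(x) > 0))
  if (!all(unlist(ok))) stop("bp must be strictly increasing within each lg")
  rownames(geno) <- markers$marker
  structure(list(markers = markers[, c("marker", "lg", "bp")], geno = geno,
                 individuals = colnames(geno), mother = mother,
                 father = father), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d markers on %d linkage groups, %d individuals (parents %s x %s)\n",
              nrow(x$markers), length(unique(x$markers$lg)),
              length(x$individuals), x$mother, x$father))
  invisible(x)
}

#' Progeny ids of a genotype matrix
#' @param gm a `geno_matrix`.
#' @return character vector of individual ids excluding the parents.
#' @export
progeny_ids <- function(gm) setdiff(gm$individuals, c(gm$mother, gm$father))

#' Classify markers by pseudo-testcross informativeness
#'
#' A marker is informative for linkage phasing when it is heterozygous in
#' exactly one parent and homozygous in the other: that parent's two
#' alleles then segregate 1:1 in the progeny, so the transmitted haplotype
#' can be read off each progeny genotype. The classification depends only
#' on the two parental calls:
#' * `MATERNAL_INFORMATIVE` — mother het, father hom;
#' * `PATERNAL_INFORMATIVE` — father het, mother hom;
#' * `BOTH_HET` — both het (transmission ambiguous; excluded from phasing);
#' * `UNINFORMATIVE` — both hom;
#' * `UNUSABLE` — a parent call missing, or more than two alleles observed
#'   across the parents (with a warning).
#'
#' @param gm a [geno_matrix()].
#' @return data frame `marker`, `lg`, `bp`, `class`.
#' @export
classify_markers <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  mo <- gm$geno[, gm$mother]
  fa <- gm$geno[, gm$father]
  mo_al <- split_geno(mo); fa_al <- split_geno(fa)
  n_alleles <- vapply(seq_along(mo), function(j) {
    length(unique(stats::na.omit(c(mo_al[j, ], fa_al[j, ]))))
  }, 0L)
  mo_het <- !is.na(mo_al[, 1L]) & mo_al[, 1L] != mo_al[, 2L]
  fa_het <- !is.na(fa_al[, 1L]) & fa_al[, 1L] != fa_al[, 2L]
  missing_parent <- is.na(mo_al[, 1L]) | is.na(fa_al[, 1L])
  multi <- !missing_parent & n_alleles > 2L
  if (any(multi)) {
    warning(sum(multi), " marker(s) with >2 parental alleles set UNUSABLE")
  }
  cls <- ifelse(missing_parent | multi, "UNUSABLE",
         ifelse(mo_het & !fa_het, "MATERNAL_INFORMATIVE",
         ifelse(fa_het & !mo_het, "PATERNAL_INFORMATIVE",
         ifelse(mo_het & fa_het, "BOTH_HET", "UNINFORMATIVE"))))
  data.frame(marker = gm$markers$marker, lg = gm$markers$lg,
             bp = gm$markers$bp, class = cls, stringsAsFactors = FALSE)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an uncompressed VCFv4.2 file: `CHROM` = linkage group, `POS` = bp,
#' `ID` = marker id, unphased `GT` calls (`0/1` style, `./.` for missing).
#' `REF` is the first allele observed across individuals at the marker.
#'
#' @param gm a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  m <- nrow(gm$markers)
  lines <- character(m)
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$individuals), collapse = "\t"))
  for (j in seq_len(m)) {
    al <- split_geno(gm$geno[j, ])
    obs <- unique(as.vector(t(al)))
    obs <- obs[!is.na(obs)]
    if (!length(obs)) obs <- "N"
    ref <- obs[1L]
    alt <- if (length(obs) > 1L) obs[-1L] else "."
    gt <- apply(al, 1L, function(a) {
      if (is.na(a[1L])) "./." else
        paste(match(a, obs) - 1L, collapse = "/")
    })
    lines[j] <- paste(c(gm$markers$lg[j], gm$markers$bp[j],
                        gm$markers$marker[j], ref,
                        paste(alt, collapse = ","), ".", "PASS", ".", "GT",
                        gt), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a genotype matrix from a VCF
#'
#' Parses with `vcfR`; `CHROM` is taken as the linkage group and `POS` as
#' the bp position. Genotypes are decoded back to allele pairs; unphased
#' and phased separators are both accepted (phase is discarded).
#'
#' @param path VCF path.
#' @param mother,father sample names of the two parents.
#' @return a [geno_matrix()].
#' @export
read_genotypes_vcf <- function(path, mother, father) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- strsplit(paste(fix[, "REF"], fix[, "ALT"], sep = ","), ",",
                      fixed = TRUE)
  m <- nrow(gt)
  out <- matrix(NA_character_, m, ncol(gt), dimnames = dimnames(gt))
  for (j in seq_len(m)) {
    a <- alleles[[j]]
    codes <- strsplit(gt[j, ], "[/|]")
    out[j, ] <- vapply(codes, function(cd) {
      if (length(cd) != 2L || any(is.na(cd)) || any(cd == ".")) {
        NA_character_
      } else {
        join_geno(a[as.integer(cd[1L]) + 1L], a[as.integer(cd[2L]) + 1L])
      }
    }, "")
  }
  markers <- data.frame(marker = fix[, "ID"], lg = fix[, "CHROM"],
                        bp = as.integer(fix[, "POS"]),
                        stringsAsFactors = FALSE)
  o <- order(markers$lg, markers$bp)
  geno_matrix(markers[o, ], out[o, , drop = FALSE], mother, father)
}

#' Write / read a genotype matrix as TSV
#'
#' Tabular dialect: columns `marker`, `lg`, `bp`, then one column per
#' individual holding `"A/G"`-style calls with `./.` for missing.
#'
#' @param gm a [geno_matrix()].
#' @param path file path.
#' @param mother,father parent column names (reader).
#' @return `path` (writer, invisibly) or a [geno_matrix()] (reader).
#' @export
write_genotypes_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  g <- gm$geno
  g[is.na(g)] <- "./."
  df <- cbind(gm$markers, as.data.frame(g, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path, mother, father) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  markers <- df[, c("marker", "lg", "bp")]
  g <- as.matrix(df[, setdiff(names(df), c("marker", "lg", "bp")),
                    drop = FALSE])
  g[g == "./." | g == "."] <- NA
  rownames(g) <- markers$marker
  geno_matrix(markers, g, mother, father)
}

#' Read a phenotype table
#'
#' Two-column TSV (`individual`, `trait`). When a genotype matrix is
#' supplied, phenotype rows whose individual is absent from it are dropped
#' with a message reporting the count.
#'
#' @param path TSV path.
#' @param geno optional [geno_matrix()] used to validate individual ids.
#' @return data frame `individual`, `trait`.
#' @export
read_phenotypes <- function(path, geno = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("individual", "trait")
  if (anyDuplicated(df$individual)) stop("duplicate individual ids in phenotype table")
  df$trait <- as.numeric(df$trait)
  if (!is.null(geno)) {
    unknown <- !df$individual %in% geno$individuals
    if (any(unknown)) {
      message("dropping ", sum(unknown),
              " phenotype row(s) with no matching genotype")
      df <- df[!unknown, ]
    }
  }
  df
}

#' @rdname read_phenotypes
#' @param pheno phenotype data frame.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
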