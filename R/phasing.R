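#' Allele-level transmission calls at informative markers
#'
#' At a marker informative for one parent (het in that parent, hom in the
#' other), the homozygous parent contributes its allele obligately, so the
#' transmitted allele from the informative parent is the progeny call minus
#' that obligate allele. A progeny call that cannot be produced by the two
#' parental genotypes is flagged as a Mendelian inconsistency and recorded
#' as unknown (never fatal).
#'
#' @param gm a [geno_matrix()].
#' @param classes output of [classify_markers()].
#' @param parent `"maternal"` or `"paternal"`: which parent's transmissions
#'   to extract (markers informative for that parent only).
#' @return list with `markers` (metadata of the informative markers, plus
#'   the het parent's two alleles `a1`/`a2`), `alleles` (markers x progeny
#'   character matrix of transmitted alleles), `mendel_error` (logical
#'   matrix flagging inconsistent calls).
#' @export
raw_transmission <- function(gm, classes, parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  want <- if (parent == "maternal") "MATERNAL_INFORMATIVE" else "PATERNAL_INFORMATIVE"
  idx <- which(classes$class == want)
  prog <- progeny_ids(gm)
  het_col <- if (parent == "maternal") gm$mother else gm$father
  hom_col <- if (parent == "maternal") gm$father else gm$mother
  het_al <- split_geno(gm$geno[idx, het_col])
  hom_al <- split_geno(gm$geno[idx, hom_col])[, 1L]
  al <- matrix(NA_character_, length(idx), length(prog),
               dimnames = list(gm$markers$marker[idx], prog))
  err <- matrix(FALSE, length(idx), length(prog),
                dimnames = dimnames(al))
  child <- gm$geno[idx, prog, drop = FALSE]
  for (j in seq_along(idx)) {
    a1 <- het_al[j, 1L]; a2 <- het_al[j, 2L]; h <- hom_al[j]
    cal <- split_geno(child[j, ])
    for (i in seq_along(prog)) {
      c1 <- cal[i, 1L]; c2 <- cal[i, 2L]
      if (is.na(c1)) next
      if (c1 == h) tr <- c2
      else if (c2 == h) tr <- c1
      else { err[j, i] <- TRUE; next }      # obligate allele absent
      if (tr != a1 && tr != a2) { err[j, i] <- TRUE; next }
      al[j, i] <- tr
    }
  }
  mk <- cbind(gm$markers[idx, , drop = FALSE],
              a1 = het_al[, 1L], a2 = het_al[, 2L])
  rownames(mk) <- NULL
  list(markers = mk, alleles = al, mendel_error = err, parent = parent)
}

#' Phase a parent's informative markers by greedy co-segregation
#'
#' The two alleles of the informative parent at each marker are mapped onto
#' haplotype labels 1/2 by choosing, marker by marker along each linkage
#' group, the orientation that minimises apparent recombinations against
#' the previous oriented marker (majority co-segregation over progeny pairs
#' with both calls present). The first marker of a linkage group is
#' oriented arbitrarily, so solutions are defined up to a per-LG 1<->2
#' label switch. A tie in the co-segregation vote keeps the current
#' orientation and flags the marker low-confidence.
#'
#' With complete data the total apparent-recombination count decomposes
#' over adjacent marker pairs, so this greedy pass attains the global
#' minimum-recombination phase.
#'
#' @param raw output of [raw_transmission()].
#' @return an object of class `transmission_matrix`: list with `markers`
#'   (metadata plus `hap1_allele` giving the allele assigned to haplotype 1
#'   and `low_confidence` flag), `tm` (markers x progeny integer matrix of
#'   transmitted haplotype labels 1/2, `NA` unknown), `parent`.
#' @export
phase_parent <- function(raw) {
  mk <- raw$markers
  # allele -> provisional label: 1 if equal to a1, 2 if a2
  z <- matrix(NA_integer_, nrow(mk), ncol(raw$alleles),
              dimnames = dimnames(raw$alleles))
  z[raw$alleles == mk$a1[row(raw$alleles)]] <- 1L
  z[raw$alleles == mk$a2[row(raw$alleles)]] <- 2L
  flip <- logical(nrow(mk))
  lowc <- logical(nrow(mk))
  for (lg in unique(mk$lg)) {
    rows <- which(mk$lg == lg)
    if (length(rows) < 2L) next
    prev <- z[rows[1L], ]
    for (r in rows[-1L]) {
      cur <- z[r, ]
      ok <- !is.na(prev) & !is.na(cur)
      agree <- sum(prev[ok] == cur[ok])
      disagree <- sum(ok) - agree
      if (disagree > agree) {
        flip[r] <- TRUE
        cur <- 3L - cur
      } else if (disagree == agree) {
        lowc[r] <- TRUE
      }
      prev <- cur
    }
  }
  tm <- z
  tm[flip, ] <- 3L - z[flip, , drop = FALSE]
  mk$hap1_allele <- ifelse(flip, mk$a2, mk$a1)
  mk$low_confidence <- lowc
  structure(list(markers = mk, tm = tm, parent = raw$parent),
            class = "transmission_matrix")
}

#' @export
print.transmission_matrix <- function(x, ...) {
  cat(sprintf("transmission_matrix (%s): %d informative markers x %d progeny, %d low-confidence\n",
              x$parent, nrow(x$tm), ncol(x$tm), sum(x$markers$low_confidence)))
  invisible(x)
}

#' Count apparent recombinations in a transmission matrix
#'
#' Total number of label switches between consecutive non-missing markers
#' within a linkage group, summed over progeny. Used as the phasing
#' objective and by the exhaustive phasing oracle in the test suite.
#'
#' @param tm integer matrix of labels (1/2/`NA`), markers ordered by bp.
#' @param lg optional factor/vector splitting rows into linkage groups.
#' @return integer count.
#' @export
count_recombinations <- function(tm, lg = NULL) {
  if (is.null(lg)) lg <- rep(1L, nrow(tm))
  tot <- 0L
  for (g in unique(lg)) {
    sub <- tm[lg == g, , drop = FALSE]
    for (i in seq_len(ncol(sub))) {
      v <- sub[, i]
      v <- v[!is.na(v)]
      if (length(v) > 1L) tot <- tot + sum(diff(v) != 0L)
    }
  }
  tot
}

#' Detect recombination breakpoints from phased transmissions
#'
#' Haplotype-label runs shorter than `min_run` are masked to unknown first
#' (smoothing against isolated miscalls, as expected in low-coverage skim
#' genotyping), then a breakpoint is reported at every remaining 1<->2
#' switch between consecutive non-missing markers. Breakpoints are
#' intervals between informative-marker positions — the resolution limit of
#' the data — never point estimates.
#'
#' @param tmx a `transmission_matrix` from [phase_parent()].
#' @param min_run minimum run length for a haplotype block to count
#'   (default 3).
#' @return data frame `individual`, `parent`, `lg`, `start_bp`, `end_bp`,
#'   `left_marker`, `right_marker`.
#' @export
detect_breakpoints <- function(tmx, min_run = 3L) {
  stopifnot(inherits(tmx, "transmission_matrix"), min_run >= 1L)
  mk <- tmx$markers
  out <- list(); k <- 0L
  for (lg in unique(mk$lg)) {
    rows <- which(mk$lg == lg)
    bp <- mk$bp[rows]; ids <- mk$marker[rows]
    sub <- tmx$tm[rows, , drop = FALSE]
    for (i in seq_len(ncol(sub))) {
      v <- mask_short_runs(sub[, i], min_run, keep_edge_runs = TRUE)
      obs <- which(!is.na(v))
      if (length(obs) < 2L) next
      sw <- which(diff(v[obs]) != 0L)
      for (s in sw) {
        k <- k + 1L
        li <- obs[s]; ri <- obs[s + 1L]
        out[[k]] <- data.frame(
          individual = colnames(sub)[i], parent = tmx$parent, lg = lg,
          start_bp = bp[li], end_bp = bp[ri],
          left_marker = ids[li], right_marker = ids[ri],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) {
    return(data.frame(individual = character(), parent = character(),
                      lg = character(), start_bp = numeric(),
                      end_bp = numeric(), left_marker = character(),
                      right_marker = character()))
  }
  do.call(rbind, out)
}

# mask runs (of the non-missing subsequence) shorter than min_run to NA;
# with keep_edge_runs the first and last runs are exempt — a short run at
# the end of the informative span is as likely a real terminal crossover
# as a miscall, whereas an interior short run is flanked on both sides by
# the other haplotype and is overwhelmingly a miscall at low error rates
mask_short_runs <- function(v, min_run, keep_edge_runs = FALSE) {
  obs <- which(!is.na(v))
  if (!length(obs)) return(v)
  lab <- v[obs]
  r <- rle(lab)
  short <- r$lengths < min_run
  if (keep_edge_runs && length(short)) {
    short[1L] <- FALSE
    short[length(short)] <- FALSE
  }
  v[obs[rep(short, r$lengths)]] <- NA
  v
}

#' Write / read transmission matrices as TSV
#'
#' Wide layout: `marker`, `lg`, `bp`, `hap1_allele`, `low_confidence`, then
#' one column per progeny (1/2/NA).
#'
#' @param tmx a `transmission_matrix`.
#' @param path file path.
#' @param parent parent tag for the reader (`"maternal"`/`"paternal"`).
#' @return `path` (writer, invisibly) or a `transmission_matrix` (reader).
#' @export
write_transmissions <- function(tmx, path) {
  df <- cbind(tmx$markers[, c("marker", "lg", "bp", "hap1_allele",
                              "low_confidence")],
              as.data.frame(tmx$tm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transmissions
#' @export
read_transmissions <- function(path, parent) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("marker", "lg", "bp", "hap1_allele", "low_confidence")
  tm <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  mode(tm) <- "integer"
  rownames(tm) <- df$marker
  structure(list(markers = df[, meta], tm = tm, parent = parent),
            class = "transmission_matrix")
}
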