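#' Extract reference and alternate fragments around a variant
#'
#' Builds the two model inputs for a SNP: the genomic window of
#' `flank` bp on each side of the variant (`2 * flank + 1` bp total, 145 by
#' default, matching the model's fragment length), with the reference or the
#' alternate allele at the center.  The reference allele is verified against
#' the genome.
#'
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences.
#' @param chrom Contig name.
#' @param pos 1-based variant position (VCF convention).
#' @param ref,alt Single-base alleles (`alt = NULL` returns only the
#'   reference fragment).
#' @param flank Context flank in bp (default 72).
#' @return List with `ref_seq`, `alt_seq` (NULL when `alt` is), `offset`
#'   (1-based position of the variant within the fragment), `start`
#'   (0-based fragment start on the contig).
#' @export
build_variant_context <- function(genome, chrom, pos, ref, alt = NULL,
                                  flank = 72L) {
  seqs <- as_genome(genome)
  if (!chrom %in% names(seqs)) stop("unknown contig: ", chrom)
  contig <- seqs[[chrom]]
  L <- 2L * flank + 1L
  if (pos - flank < 1L || pos + flank > nchar(contig))
    stop(sprintf("window [%d, %d] exceeds contig %s (length %d)",
                 pos - flank, pos + flank, chrom, nchar(contig)))
  frag <- toupper(substr(contig, pos - flank, pos + flank))
  obs <- substr(frag, flank + 1L, flank + 1L)
  if (obs != toupper(ref))
    stop(sprintf("reference mismatch at %s:%d: expected %s, genome has %s",
                 chrom, pos, ref, obs))
  alt_seq <- NULL
  if (!is.null(alt)) {
    alt_seq <- frag
    substr(alt_seq, flank + 1L, flank + 1L) <- toupper(alt)
  }
  list(ref_seq = frag, alt_seq = alt_seq, offset = flank + 1L,
       start = pos - flank - 1L, length = L)
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  genome
}

#' Signed allelic effect of a variant
#'
#' The difference `prediction(alt) - prediction(ref)` for one task, in that
#' task's z-score units; the sign is the predicted direction of effect.
#'
#' @param model A fitted [mpra_cnn()].
#' @param ref_seq,alt_seq Fragments from [build_variant_context()].
#' @param task Task name or index.
#' @return Scalar signed effect (0 when the fragments are identical).
#' @export
variant_effect <- function(model, ref_seq, alt_seq, task = 1L) {
  ti <- task_index(model, task)
  if (identical(ref_seq, alt_seq)) return(0)
  p <- predict(model, c(ref_seq, alt_seq))
  unname(p[2, ti] - p[1, ti])
}

#' Allele-agnostic ISM score at one position
#'
#' The maximum over the three single-base substitutions at `center` of the
#' absolute prediction change `|f(mutant) - f(reference)|`.  Used when the
#' risk allele is unknown; it upper-bounds `|variant_effect|` for any
#' specific alternate allele at that position.
#'
#' @param model A fitted [mpra_cnn()].
#' @param fragment DNA string of the model's fragment length.
#' @param center 1-based position within the fragment.
#' @param task Task name or index.
#' @return Scalar (non-negative) ISM score.
#' @export
position_ism_score <- function(model, fragment, center, task = 1L) {
  L <- model$spec$fragment_length
  stopifnot(nchar(fragment) == L, center >= 1L, center <= L)
  ti <- task_index(model, task)
  chars <- strsplit(toupper(fragment), "", fixed = TRUE)[[1]]
  refb <- chars[center]
  if (!refb %in% DNA_BASES) stop("N at the scored position")
  muts <- vapply(setdiff(DNA_BASES, refb), function(b) {
    s <- chars; s[center] <- b; paste(s, collapse = "")
  }, character(1))
  p <- predict(model, c(paste(chars, collapse = ""), muts))
  max(abs(p[-1, ti] - p[1, ti]))
}

#' LD-adjusted variant scores
#'
#' Assigns each tag SNP the maximum ISM score over all members of its LD
#' block (the tag itself plus its proxies at R-squared at or above the
#' blocking threshold), recording which member attains it.  Block members
#' without a score are dropped with a count.
#'
#' @param scores Named numeric vector of per-variant ISM scores.
#' @param blocks Data frame with columns `tag_id`, `proxy_id` (one row per
#'   block member; the tag need not be listed as its own proxy).
#' @return Data frame with `tag_id`, `ld_adjusted_score`, `argmax_id`,
#'   `n_members`, `n_missing`.
#' @export
ld_adjust <- function(scores, blocks) {
  stopifnot(all(c("tag_id", "proxy_id") %in% names(blocks)),
            !is.null(names(scores)))
  tags <- unique(blocks$tag_id)
  rows <- lapply(tags, function(tg) {
    members <- unique(c(tg, blocks$proxy_id[blocks$tag_id == tg]))
    have <- members[members %in% names(scores)]
    if (!length(have))
      stop("LD block of ", tg, " has no scored members")
    sc <- scores[have]
    best <- which.max(sc)
    data.frame(tag_id = tg, ld_adjusted_score = unname(sc[best]),
               argmax_id = have[best], n_members = length(members),
               n_missing = length(members) - length(have))
  })
  do.call(rbind, rows)
}

#' Saturation mutagenesis around a position
#'
#' Evaluates every single-base substitution within `halfwidth` bp of
#' `center` (all three mutants at each of the `2 * halfwidth + 1` positions)
#' and reports the signed prediction deltas together with the per-position
#' maximum absolute change.  A window reaching past the fragment is clipped
#' with a warning.
#'
#' @param model A fitted [mpra_cnn()].
#' @param fragment DNA string of the model's fragment length.
#' @param center 1-based window center within the fragment.
#' @param halfwidth Window half-width in bp (default 25).
#' @param task Task name or index.
#' @return List with `delta` ((2*halfwidth+1) x 4 signed matrix
#'   `f(mutant) - f(reference)`, 0 at the reference base, NA at clipped
#'   positions), `positions` (1-based fragment coordinates), `max_abs`
#'   (per-position max |delta|), `f_ref`.
#' @export
saturation_mutagenesis <- function(model, fragment, center, halfwidth = 25L,
                                   task = 1L) {
  L <- model$spec$fragment_length
  stopifnot(nchar(fragment) == L, center >= 1L, center <= L)
  ti <- task_index(model, task)
  pos <- (center - halfwidth):(center + halfwidth)
  if (any(pos < 1L | pos > L)) {
    warning("saturation window clipped to the fragment")
  }
  keep <- pos >= 1L & pos <= L
  chars <- strsplit(toupper(fragment), "", fixed = TRUE)[[1]]
  muts <- character(0); map <- matrix(0L, 0, 2)
  for (w in which(keep)) {
    i <- pos[w]
    refb <- chars[i]
    if (!refb %in% DNA_BASES) next
    for (b in which(DNA_BASES != refb)) {
      s <- chars; s[i] <- DNA_BASES[b]
      muts <- c(muts, paste(s, collapse = ""))
      map <- rbind(map, c(w, b))
    }
  }
  p <- predict(model, c(paste(chars, collapse = ""), muts))
  f_ref <- p[1, ti]
  delta <- matrix(NA_real_, nrow = length(pos), ncol = 4L,
                  dimnames = list(NULL, DNA_BASES))
  for (w in which(keep)) delta[w, ] <- 0
  if (length(muts)) delta[map] <- p[-1, ti] - f_ref
  max_abs <- apply(delta, 1, function(r)
    if (all(is.na(r))) NA_real_ else max(abs(r), na.rm = TRUE))
  list(delta = delta, positions = pos, max_abs = max_abs, f_ref = f_ref,
       center = center, task = model$tasks[ti])
}

#' Prioritize variants by combining ISM scores with GWAS significance
#'
#' Filters to variants with `|score| >= score_thresh` and GWAS
#' `p <= p_thresh` (defaults 0.45 and 5e-8), sorts by absolute score
#' descending, and returns the volcano-plot table (x = score,
#' y = -log10 p) for all joinable variants.  Unmatched ids are reported and
#' excluded.
#'
#' @param scores Data frame with `variant_id` and `score` (e.g. LD-adjusted
#'   ISM scores).
#' @param gwas Data frame with `variant_id` and `p`.
#' @param score_thresh Minimum absolute score (default 0.45).
#' @param p_thresh Maximum GWAS p-value (default 5e-8).
#' @return List with `candidates` (filtered, ranked data frame), `volcano`
#'   (all joined variants with `score`, `p`, `neg_log10_p`), `n_unmatched`.
#' @export
prioritize_variants <- function(scores, gwas, score_thresh = 0.45,
                                p_thresh = 5e-8) {
  stopifnot(all(c("variant_id", "score") %in% names(scores)),
            all(c("variant_id", "p") %in% names(gwas)))
  j <- merge(scores, gwas, by = "variant_id")
  n_unmatched <- nrow(scores) - nrow(j)
  j$neg_log10_p <- -log10(j$p)
  keep <- abs(j$score) >= score_thresh & j$p <= p_thresh
  cand <- j[keep, , drop = FALSE]
  cand <- cand[order(-abs(cand$score)), , drop = FALSE]
  rownames(cand) <- NULL
  list(candidates = cand, volcano = j, n_unmatched = n_unmatched)
}

#' Compare score distributions of significant vs insignificant variants
#'
#' One-sided Mann-Whitney U test (with tie correction, via
#' [stats::wilcox.test()]) of whether the first group's scores are
#' stochastically larger, plus the ratio of group means.
#'
#' @param scores_sig Scores of GWAS-significant variants.
#' @param scores_insig Scores of insignificant variants.
#' @return List with `p`, `statistic` (U), `mean_ratio`
#'   (`mean(sig) / mean(insig)`).
#' @export
compare_score_distributions <- function(scores_sig, scores_insig) {
  if (length(scores_sig) < 3 || length(scores_insig) < 3)
    stop("need at least 3 scores in each group")
  wt <- stats::wilcox.test(scores_sig, scores_insig, alternative = "greater",
                           exact = FALSE, correct = TRUE)
  list(p = wt$p.value, statistic = unname(wt$statistic),
       mean_ratio = mean(scores_sig) / mean(scores_insig))
}
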