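#' Configuration for the synthetic tiling-MPRA simulator
#'
#' Describes a Sharpr-style benchmark: `n_regions` regulatory regions of
#' `region_length` bp, each tiled by fragments of `fragment_length` bp at
#' `tile_step` bp offsets (295/145/5 gives 31 fragments per region), with
#' cell-type- and state-specific transcription-factor motifs planted on an
#' i.i.d. background and measured in two noisy replicates per task.
#'
#' @param n_regions Number of tiled regions.
#' @param region_length Region length in bp (default 295).
#' @param fragment_length Fragment length in bp (default 145).
#' @param tile_step Tiling step in bp (default 5);
#'   `region_length - fragment_length` must be divisible by it.
#' @param motif_library Optional list of planted-motif descriptions from
#'   [default_motif_library()].
#' @param gc Background GC fraction (default 0.41, genome-like).
#' @param concordance_target Desired between-replicate Spearman correlation
#'   per task (default 0.40, typical of tiling MPRA data); replicate noise
#'   is calibrated to hit it.
#' @param baseline_sd Standard deviation of the per-region baseline
#'   activity (default 0.3).
#' @param noise_mode `"homoscedastic"` (default) or `"heteroscedastic"`
#'   (per-fragment noise scales vary, so replicate gap predicts error).
#' @param seed Mandatory RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_regions = 100L, region_length = 295L,
                       fragment_length = 145L, tile_step = 5L,
                       motif_library = NULL, gc = 0.41,
                       concordance_target = 0.40, baseline_sd = 0.3,
                       noise_mode = c("homoscedastic", "heteroscedastic"),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  noise_mode <- match.arg(noise_mode)
  if ((region_length - fragment_length) %% tile_step != 0)
    stop("(region_length - fragment_length) must be divisible by tile_step")
  stopifnot(gc > 0, gc < 1, concordance_target > 0, concordance_target <= 1)
  structure(list(n_regions = as.integer(n_regions),
                 region_length = as.integer(region_length),
                 fragment_length = as.integer(fragment_length),
                 tile_step = as.integer(tile_step),
                 motif_library = motif_library, gc = gc,
                 concordance_target = concordance_target,
                 baseline_sd = baseline_sd, noise_mode = noise_mode,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default planted-motif library for the simulator
#'
#' Twelve motifs of width 6-8 with sharp, seeded random probability
#' matrices.  Six carry activity effects and are planted by state: a
#' promoter-exclusive activator, K562- and HepG2-specific enhancer
#' activators, a shared activator, a ubiquitous weak activator, and a
#' repressor (negative effect, planted in repressed regions).  The other
#' six are inert decoys that are never planted, providing negatives for
#' usage-ranking analyses.  Effects are in activity units per task
#' (K562_minP, K562_SV40P, HepG2_minP, HepG2_SV40P).
#'
#' @param seed RNG seed (default 1).
#' @return List of motif descriptions: each has `pwm`, `effects` (length-4
#'   numeric), `states` (which region states it is planted in; NULL for
#'   decoys).
#' @export
default_motif_library <- function(seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)
  mk <- function(id, width) {
    dom <- stats::runif(width, 0.75, 0.97)
    cons <- sample.int(4L, width, replace = TRUE)
    m <- matrix(0, width, 4L)
    for (i in seq_len(width)) {
      m[i, ] <- (1 - dom[i]) / 3
      m[i, cons[i]] <- dom[i]
    }
    pwm(id, m, "prob")
  }
  spec <- list(
    list(id = "promA",  w = 8L, eff = c( 1.8,  1.6,  1.8,  1.6), st = "promoter"),
    list(id = "enhK",   w = 7L, eff = c( 2.0,  1.7,  0.0,  0.0), st = "enhancer"),
    list(id = "enhH",   w = 7L, eff = c( 0.0,  0.0,  2.0,  1.7), st = "enhancer"),
    list(id = "enhAB",  w = 6L, eff = c( 1.5,  1.3,  1.5,  1.3), st = c("enhancer", "other")),
    list(id = "ubiqW",  w = 6L, eff = c( 0.8,  0.7,  0.8,  0.7), st = c("promoter", "enhancer", "repressed", "other")),
    list(id = "repR",   w = 8L, eff = c(-1.8, -1.5, -1.8, -1.5), st = "repressed"),
    list(id = "decoy1", w = 7L, eff = rep(0, 4), st = NULL),
    list(id = "decoy2", w = 6L, eff = rep(0, 4), st = NULL),
    list(id = "decoy3", w = 8L, eff = rep(0, 4), st = NULL),
    list(id = "decoy4", w = 7L, eff = rep(0, 4), st = NULL),
    list(id = "decoy5", w = 6L, eff = rep(0, 4), st = NULL),
    list(id = "decoy6", w = 8L, eff = rep(0, 4), st = NULL))
  lapply(spec, function(s)
    list(pwm = mk(s$id, s$w), effects = stats::setNames(s$eff, mpra_tasks()),
         states = s$st))
}

## Geometric-mean match fraction of a planted/observed instance sequence to
## its PWM (1 at consensus, decreasing with mismatches weighted by position
## information).
pwm_match_frac <- function(seq, x) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  stopifnot(length(chars) == x$width)
  bi <- match(chars, DNA_BASES)
  p <- pmax(x$matrix[cbind(seq_len(x$width), bi)], 1e-3)
  pmaxv <- apply(x$matrix, 1, max)
  exp(mean(log(p) - log(pmaxv)))
}

random_dna <- function(n, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

## Calibrate a per-task noise sd so that Spearman(truth + sd*e1,
## truth + sd*e2) hits the target, by bisection on pre-drawn unit noise.
calibrate_noise_sd <- function(truth, target, e1, e2, tol = 0.002) {
  rho_at <- function(sd) stats::cor(truth + sd * e1, truth + sd * e2,
                                    method = "spearman")
  lo <- 0; hi <- stats::sd(truth) * 0.5 + 1e-6
  while (rho_at(hi) > target) hi <- hi * 2
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    r <- rho_at(mid)
    if (abs(r - target) < tol) return(mid)
    if (r > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a tiled MPRA dataset with known ground truth
#'
#' Draws i.i.d. background regions at the configured GC fraction, samples a
#' chromatin state per region, plants motif instances from the library's
#' probability matrices at random non-overlapping positions (at least 5 bp
#' apart, fully inside the region), tiles each region into fragments, and
#' assigns each fragment a true activity: the region baseline plus the sum
#' of effects of all motif instances fully contained in the fragment, where
#' an instance's realized effect is its motif's per-task effect scaled by
#' how well the sampled instance matches the consensus.  Two replicates per
#' task are produced by adding Gaussian noise whose scale is calibrated by
#' bisection so the realized between-replicate Spearman correlation matches
#' `concordance_target`.  Everything is deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `dataset` (an [mpra_dataset()]; fragments carry
#'   `region_id`, `tile_offset` and `state`), `truth` (instances table,
#'   per-fragment true activity matrix, region sequences/states, baselines,
#'   motif library, calibrated noise sd per task), and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(cfg$seed)

  lib <- cfg$motif_library
  if (is.null(lib)) lib <- default_motif_library(seed = cfg$seed)
  wmax <- max(vapply(lib, function(m) m$pwm$width, integer(1)))
  if (wmax > cfg$fragment_length) stop("motif longer than fragment")
  tasks <- mpra_tasks()
  states <- c("promoter", "enhancer", "repressed", "other")
  state_probs <- c(0.25, 0.35, 0.2, 0.2)
  planted_in <- lapply(states, function(st)
    which(vapply(lib, function(m) st %in% m$states, logical(1))))
  names(planted_in) <- states

  nreg <- cfg$n_regions
  RL <- cfg$region_length; FL <- cfg$fragment_length; TS <- cfg$tile_step
  n_tiles <- (RL - FL) %/% TS + 1L
  region_id <- sprintf("region%05d", seq_len(nreg))
  chroms <- paste0("chr", rep_len(1:22, nreg))
  region_state <- sample(states, nreg, replace = TRUE, prob = state_probs)
  baseline <- stats::rnorm(nreg, 0, cfg$baseline_sd)

  region_seq <- character(nreg)
  inst <- list()
  for (r in seq_len(nreg)) {
    seq_chars <- strsplit(random_dna(RL, cfg$gc), "", fixed = TRUE)[[1]]
    pool <- planted_in[[region_state[r]]]
    n_inst <- if (region_state[r] == "other") stats::rpois(1, 0.7) else
      min(1L + stats::rpois(1, 1.2), 4L)
    used <- matrix(0L, 0, 2)            # occupied [start, end) spans
    for (k in seq_len(n_inst)) {
      if (!length(pool)) break
      mi <- pool[sample.int(length(pool), 1L)]
      w <- lib[[mi]]$pwm$width
      ok_pos <- NULL
      for (try in 1:20) {
        s0 <- sample.int(RL - w + 1L, 1L) - 1L     # 0-based start
        clash <- nrow(used) && any(s0 < used[, 2] + 5L & s0 + w + 5L > used[, 1])
        if (!clash) { ok_pos <- s0; break }
      }
      if (is.null(ok_pos)) next
      strand <- sample(c("+", "-"), 1L)
      pm <- lib[[mi]]$pwm
      draw <- vapply(seq_len(pm$width), function(i)
        sample(DNA_BASES, 1L, prob = pm$matrix[i, ]), character(1))
      inst_seq <- paste(draw, collapse = "")
      mf <- pwm_match_frac(inst_seq, pm)
      placed <- if (strand == "+") inst_seq else revcomp_seq(inst_seq)
      seq_chars[(ok_pos + 1L):(ok_pos + pm$width)] <-
        strsplit(placed, "", fixed = TRUE)[[1]]
      used <- rbind(used, c(ok_pos, ok_pos + pm$width))
      inst[[length(inst) + 1L]] <- data.frame(
        region_id = region_id[r], motif_id = pm$motif_id, start = ok_pos,
        end = ok_pos + pm$width, strand = strand, match_frac = mf,
        t(lib[[mi]]$effects * mf))
    }
    region_seq[r] <- paste(seq_chars, collapse = "")
  }
  instances <- if (length(inst)) do.call(rbind, inst) else
    data.frame(region_id = character(0), motif_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               match_frac = numeric(0))
  names(region_seq) <- region_id

  ## tile fragments and accumulate ground-truth activity
  nfrag <- nreg * n_tiles
  offs <- (seq_len(n_tiles) - 1L) * TS
  frag_region <- rep(seq_len(nreg), each = n_tiles)
  frag_off <- rep(offs, times = nreg)
  frag_id <- paste0(region_id[frag_region], "_t",
                    sprintf("%02d", rep(seq_len(n_tiles), times = nreg)))
  frag_seq <- substring(region_seq[frag_region], frag_off + 1L, frag_off + FL)
  truth <- matrix(rep(baseline[frag_region], length(tasks)), ncol = length(tasks),
                  dimnames = list(frag_id, tasks))
  if (nrow(instances)) {
    for (j in seq_len(nrow(instances))) {
      ri <- match(instances$region_id[j], region_id)
      hit <- which(frag_region == ri &
                     frag_off <= instances$start[j] &
                     frag_off + FL >= instances$end[j])
      if (length(hit))
        truth[hit, ] <- truth[hit, ] +
          rep(as.numeric(instances[j, tasks]), each = length(hit))
    }
  }

  ## replicate noise calibrated to the concordance target
  scale_frag <- if (cfg$noise_mode == "heteroscedastic")
    sqrt(stats::rgamma(nfrag, shape = 2, rate = 2)) else rep(1, nfrag)
  noise_sd <- numeric(length(tasks))
  rep1 <- rep2 <- truth
  for (t in seq_along(tasks)) {
    e1 <- stats::rnorm(nfrag) * scale_frag
    e2 <- stats::rnorm(nfrag) * scale_frag
    noise_sd[t] <- calibrate_noise_sd(truth[, t], cfg$concordance_target,
                                      e1, e2)
    rep1[, t] <- truth[, t] + noise_sd[t] * e1
    rep2[, t] <- truth[, t] + noise_sd[t] * e2
  }
  names(noise_sd) <- tasks
  labels <- (rep1 + rep2) / 2

  start <- 10000L + (frag_region - 1L) * 1000L + frag_off
  fragments <- data.frame(
    fragment_id = frag_id, chrom = chroms[frag_region], start = start,
    end = start + FL, strand = "+", sequence = unname(frag_seq),
    region_id = region_id[frag_region], tile_offset = frag_off,
    state = region_state[frag_region])
  ds <- mpra_dataset(fragments, labels, replicates = list(rep1, rep2),
                     fragment_length = FL)
  list(dataset = ds,
       truth = list(instances = instances, activity = truth,
                    region_seq = region_seq, region_state =
                      stats::setNames(region_state, region_id),
                    baseline = stats::setNames(baseline, region_id),
                    motif_library = lib, noise_sd = noise_sd),
       config = cfg)
}

#' Simulate variants, LD blocks and GWAS statistics over a simulated dataset
#'
#' Places causal variants inside planted motif instances (the substitution
#' at a motif's most informative position toward its least likely base,
#' whose true allelic effect is the induced change in the additive ground
#' truth) and null variants in background positions.  Each LD block has a
#' null background variant as its tag; in a `prop_causal` fraction of
#' blocks a causal variant is included as a proxy, so the tag itself never
#' carries the effect.  GWAS p-values are drawn genome-wide significant for
#' causal blocks and null (> 0.1) otherwise.
#'
#' @param sim Result of [simulate_dataset()].
#' @param n_blocks Number of LD blocks.
#' @param prop_causal Fraction of blocks containing a causal proxy, in
#'   `(0, 1]` (use a small positive value and ignore flags for pure nulls).
#' @param flank Context flank used downstream (default 72); variants are
#'   placed so the full window fits in the region.
#' @param seed RNG seed (default: the simulation's seed + 1).
#' @return List with `variants` (variant_id, chrom = region contig, pos
#'   1-based, ref, alt, is_causal, per-task `true_effect_*`), `ld` (tag_id,
#'   proxy_id, r2), `gwas` (variant_id, p), and `genome` (named contig
#'   sequences).
#' @export
simulate_variants <- function(sim, n_blocks = 200L, prop_causal = 0.5,
                              flank = 72L, seed = NULL) {
  stopifnot(is.list(sim), !is.null(sim$truth))
  if (prop_causal <= 0 || prop_causal > 1)
    stop("prop_causal must be in (0, 1]")
  if (is.null(seed)) seed <- sim$config$seed + 1L
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)

  genome <- sim$truth$region_seq
  RL <- sim$config$region_length
  lo <- flank + 1L; hi <- RL - flank
  if (hi < lo) stop("regions too short for the requested flank")
  inst <- sim$truth$instances
  lib <- sim$truth$motif_library
  lib_ids <- vapply(lib, function(m) m$pwm$motif_id, character(1))
  tasks <- mpra_tasks()

  ## candidate causal instances: effectful motif, fully inside the scoring window
  eff_ok <- vapply(lib, function(m) any(m$effects != 0), logical(1))
  cand <- which(inst$motif_id %in% lib_ids[eff_ok] &
                  inst$start >= lo - 1L & inst$end <= hi)
  n_causal <- round(prop_causal * n_blocks)
  if (length(cand) < n_causal)
    stop("not enough planted instances for the requested causal blocks")
  cand <- sample(cand, n_causal)

  occupied <- split(inst[, c("start", "end")], inst$region_id)
  draw_null <- function() {
    repeat {
      ri <- sample(names(genome), 1L)
      pos <- sample(lo:hi, 1L)          # 1-based
      occ <- occupied[[ri]]
      if (!is.null(occ) && any(pos - 1L >= occ$start & pos - 1L < occ$end))
        next
      refb <- substr(genome[[ri]], pos, pos)
      alt <- sample(setdiff(DNA_BASES, refb), 1L)
      return(list(chrom = ri, pos = pos, ref = refb, alt = alt))
    }
  }

  vid <- 0L
  new_id <- function() { vid <<- vid + 1L; sprintf("rs%06d", vid) }
  vars <- list(); ld <- list(); gwas <- list()
  zero_eff <- stats::setNames(rep(0, length(tasks)),
                              paste0("true_effect_", tasks))
  add_var <- function(v, causal, eff) {
    id <- new_id()
    vars[[length(vars) + 1L]] <<- data.frame(
      variant_id = id, chrom = v$chrom, pos = v$pos, ref = v$ref,
      alt = v$alt, is_causal = causal, t(eff))
    id
  }

  for (b in seq_len(n_blocks)) {
    causal_block <- b <= n_causal
    tag <- add_var(draw_null(), FALSE, zero_eff)
    proxies <- character(0)
    if (causal_block) {
      j <- cand[b]
      mi <- match(inst$motif_id[j], lib_ids)
      pm <- lib[[mi]]$pwm
      info <- apply(pm$matrix, 1, max)
      ## most informative column at which this instance carries the
      ## consensus base, so substituting the least likely base is
      ## guaranteed to weaken the match
      iseq0 <- substr(genome[[inst$region_id[j]]], inst$start[j] + 1L,
                      inst$end[j])
      iseq0 <- if (inst$strand[j] == "+") iseq0 else revcomp_seq(iseq0)
      cons <- max.col(pm$matrix, ties.method = "first")
      at_cons <- which(strsplit(iseq0, "", fixed = TRUE)[[1]] ==
                         DNA_BASES[cons])
      col <- if (length(at_cons)) at_cons[which.max(info[at_cons])] else
        which.max(info)
      ## map motif column to genomic position, strand-aware
      gpos <- if (inst$strand[j] == "+") inst$start[j] + col else
        inst$end[j] - col + 1L
      refb <- substr(genome[[inst$region_id[j]]], gpos, gpos)
      worst <- DNA_BASES[which.min(pm$matrix[col, ])]
      altb <- if (inst$strand[j] == "+") worst else revcomp_seq(worst)
      if (altb == refb) altb <- sample(setdiff(DNA_BASES, refb), 1L)
      ## true effect: change in realized additive effect of this instance
      iseq <- substr(genome[[inst$region_id[j]]], inst$start[j] + 1L,
                     inst$end[j])
      iseq_fwd <- if (inst$strand[j] == "+") iseq else revcomp_seq(iseq)
      alt_region_pos <- gpos - inst$start[j]          # 1-based within instance
      alt_inst_pos <- if (inst$strand[j] == "+") alt_region_pos else
        pm$width - alt_region_pos + 1L
      alt_seq <- iseq_fwd
      substr(alt_seq, alt_inst_pos, alt_inst_pos) <-
        if (inst$strand[j] == "+") altb else revcomp_seq(altb)
      dmf <- pwm_match_frac(alt_seq, pm) - pwm_match_frac(iseq_fwd, pm)
      eff <- stats::setNames(lib[[mi]]$effects * dmf,
                             paste0("true_effect_", tasks))
      proxies <- c(proxies, add_var(list(chrom = inst$region_id[j],
                                         pos = gpos, ref = refb, alt = altb),
                                    TRUE, eff))
    }
    for (k in seq_len(sample(0:2, 1L)))
      proxies <- c(proxies, add_var(draw_null(), FALSE, zero_eff))
    for (p in proxies)
      ld[[length(ld) + 1L]] <- data.frame(tag_id = tag, proxy_id = p,
                                          r2 = stats::runif(1, 0.8, 1))
    gwas[[length(gwas) + 1L]] <- data.frame(
      variant_id = tag,
      p = if (causal_block) 10^(-stats::runif(1, 8.5, 20)) else
        stats::runif(1, 0.15, 1))
  }
  list(variants = do.call(rbind, vars),
       ld = if (length(ld)) do.call(rbind, ld) else
         data.frame(tag_id = character(0), proxy_id = character(0),
                    r2 = numeric(0)),
       gwas = do.call(rbind, gwas),
       genome = genome, flank = flank, seed = seed)
}
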