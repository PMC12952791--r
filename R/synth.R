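# Seeded synthetic-data generators: scripted pose sequences with
# ground-truth ethograms, annotator-pair label noise, and strain panels with
# known genetic architecture. Every generator is a pure function of its
# parameters and seed.
#
# The kinematics are deliberately simple (rigid body plus oscillation):
# their job is to make scripted behaviors separable in the documented
# feature space, not to be biomechanically realistic. Defaults mirror the
# recording convention of the platform being emulated: 30 fps, 800 x 800 px
# arena, and a 7 Hz oscillation for grooming-like bouts (the data capture
# rate must be at least twice the event frequency, so generators enforce a
# Nyquist guard against the stated fps).

#' Behavior script for pose synthesis
#'
#' @param behavior Behavior name (defaults to the kinematic id).
#' @param kinematic One of "turn_left", "turn_right", "groom", "rear_proxy",
#'   "idle".
#' @param bout_frames Length-2 range (frames) from which bout durations are
#'   drawn uniformly.
#' @param gap_frames Length-2 range (frames) for inter-bout idle gaps.
#' @param angular_speed Turn angular speed, rad/s (default 2).
#' @param osc_freq Oscillation frequency for groom bouts, Hz (default 7;
#'   must stay below fps/2).
#' @param jitter_px Keypoint jitter standard deviation, pixels (default 0.3,
#'   the sub-pixel scale of a modern pose estimator).
#' @return Object of class `BehaviorScript`.
#' @export
behavior_script <- function(behavior = NULL,
                            kinematic = c("turn_left", "turn_right", "groom",
                                          "rear_proxy", "idle"),
                            bout_frames = c(15, 90),
                            gap_frames = c(30, 150),
                            angular_speed = 2, osc_freq = 7,
                            jitter_px = 0.3) {
  kinematic <- match.arg(kinematic)
  if (any(bout_frames < 1) || bout_frames[2] < bout_frames[1])
    stop("bout_frames must be an increasing range of durations >= 1")
  if (any(gap_frames < 1) || gap_frames[2] < gap_frames[1])
    stop("gap_frames must be an increasing range of durations >= 1")
  if (osc_freq <= 0) stop("osc_freq must be positive")
  structure(list(behavior = behavior %||% kinematic, kinematic = kinematic,
                 bout_frames = as.integer(bout_frames),
                 gap_frames = as.integer(gap_frames),
                 angular_speed = angular_speed, osc_freq = osc_freq,
                 jitter_px = jitter_px),
            class = "BehaviorScript")
}

# rigid 12-keypoint mouse template in body coordinates (px), nose along +x
mouse_template <- function() {
  rbind(nose          = c(70, 0),
        left_ear      = c(55, -12),
        right_ear     = c(55, 12),
        base_neck     = c(45, 0),
        left_forepaw  = c(30, -18),
        right_forepaw = c(30, 18),
        mid_spine     = c(20, 0),
        left_hind_paw = c(0, -22),
        right_hind_paw = c(0, 22),
        base_tail     = c(-10, 0),
        mid_tail      = c(-35, 0),
        tip_tail      = c(-60, 0))
}

#' Synthesize a scripted pose sequence
#'
#' A semi-Markov alternation of idle stretches and scripted bouts drives a
#' rigid 12-keypoint mouse around an `arena_px` square arena. Turn bouts
#' rotate the body axis at the scripted angular speed; groom bouts hold the
#' centroid still while nose and forepaws oscillate at the scripted
#' frequency; rear bouts contract the body outline. The ground-truth
#' ethogram marks scripted bout frames.
#'
#' @param script A [behavior_script()].
#' @param n_frames Number of frames (`>= 2`).
#' @param fps Frames per second (default 30; must exceed twice the script's
#'   oscillation frequency).
#' @param seed Integer seed.
#' @param arena_px Arena side length in pixels (default 800).
#' @return List: `pose` (a `PoseSequence`) and `truth` (an `Ethogram`).
#' @export
synth_pose <- function(script, n_frames = 1800, fps = 30, seed = 1,
                       arena_px = 800) {
  stopifnot(inherits(script, "BehaviorScript"))
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (script$osc_freq >= fps / 2)
    stop("script oscillation frequency ", script$osc_freq,
         " Hz violates the Nyquist guard for fps = ", fps)
  set.seed(seed)
  template <- mouse_template()
  n_kp <- nrow(template)

  # schedule: idle gap, bout, idle gap, ...
  truth <- integer(n_frames)
  if (script$kinematic != "idle") {
    t <- sample(script$gap_frames[1]:script$gap_frames[2], 1L)
    while (t < n_frames) {
      len <- sample(script$bout_frames[1]:script$bout_frames[2], 1L)
      hi <- min(n_frames, t + len)
      truth[(t + 1L):hi] <- 1L
      t <- hi + sample(script$gap_frames[1]:script$gap_frames[2], 1L)
    }
  }

  margin <- 100
  pos <- runif(2, margin, arena_px - margin)
  theta <- runif(1, -pi, pi)
  walk_speed <- 40 / fps                       # px per frame while idle
  turn_sign <- if (script$kinematic == "turn_right") -1 else 1

  kp <- array(0, dim = c(n_frames, n_kp, 2))
  phase <- runif(1, 0, 2 * pi)
  for (f in seq_len(n_frames)) {
    in_bout <- truth[f] == 1L
    if (in_bout && script$kinematic %in% c("turn_left", "turn_right")) {
      theta <- theta + turn_sign * script$angular_speed / fps
    } else if (!in_bout || script$kinematic == "idle") {
      # gentle meander; near walls, steer smoothly toward the arena center
      # (no instantaneous heading jumps, which would masquerade as turns)
      theta <- theta + rnorm(1, 0, 0.02 / sqrt(fps))   # ~0.1 rad/s wander
      near_wall <- pos[1] < margin || pos[1] > arena_px - margin ||
        pos[2] < margin || pos[2] > arena_px - margin
      if (near_wall) {
        to_center <- atan2(arena_px / 2 - pos[2], arena_px / 2 - pos[1])
        dtheta <- wrap_angle(to_center - theta)
        theta <- theta + sign(dtheta) * min(abs(dtheta), 0.3 / fps)
      }
      step <- abs(rnorm(1, walk_speed, walk_speed / 2))
      pos <- pos + step * c(cos(theta), sin(theta))
      pos <- pmin(pmax(pos, margin / 2), arena_px - margin / 2)
    }
    body <- template
    if (in_bout && script$kinematic == "groom") {
      osc <- 8 * sin(2 * pi * script$osc_freq * (f / fps) + phase)
      body["nose", 1] <- body["nose", 1] - 12 + osc
      body[c("left_forepaw", "right_forepaw"), 1] <-
        body[c("left_forepaw", "right_forepaw"), 1] + osc / 2
    }
    if (in_bout && script$kinematic == "rear_proxy") body <- body * 0.55
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    pts <- body %*% t(rot)
    pts <- sweep(pts, 2, pos, "+")
    pts <- pts + matrix(rnorm(2 * n_kp, 0, script$jitter_px), n_kp, 2)
    kp[f, , ] <- pmin(pmax(pts, 0), arena_px)
  }
  conf <- matrix(runif(n_frames * n_kp, 0.85, 1), n_frames, n_kp)
  pose <- pose_sequence(kp, conf, fps = fps)
  list(pose = pose,
       truth = ethogram(truth, fps = fps, behavior_name = script$behavior,
                        source = "synth_truth"))
}

#' Annotator noise model
#'
#' @param dilation Signed boundary dilation in frames (positive widens every
#'   bout on both sides, emulating an annotator who labels more frames as
#'   behavior).
#' @param jitter_sd Standard deviation of per-boundary jitter (frames).
#' @param false_rate Expected number of spurious short bouts per 1000
#'   frames.
#' @param false_len Length-2 range of spurious bout lengths (default 1-3
#'   frames).
#' @param miss_prob Probability of dropping a true bout entirely.
#' @return Object of class `AnnotatorNoise`.
#' @export
annotator_noise <- function(dilation = 0, jitter_sd = 0, false_rate = 0,
                            false_len = c(1, 3), miss_prob = 0) {
  if (miss_prob < 0 || miss_prob > 1) stop("miss_prob must lie in [0, 1]")
  if (false_rate < 0) stop("false_rate must be >= 0")
  if (any(false_len < 1) || false_len[2] < false_len[1])
    stop("false_len must be an increasing range of lengths >= 1")
  structure(list(dilation = dilation, jitter_sd = jitter_sd,
                 false_rate = false_rate, false_len = as.integer(false_len),
                 miss_prob = miss_prob),
            class = "AnnotatorNoise")
}

apply_annotator_noise <- function(truth_bouts, noise, n_frames) {
  keep <- runif(nrow(truth_bouts)) >= noise$miss_prob
  b <- truth_bouts[keep, , drop = FALSE]
  if (nrow(b)) {
    s <- b$start - noise$dilation + round(rnorm(nrow(b), 0, noise$jitter_sd))
    e <- b$end + noise$dilation + round(rnorm(nrow(b), 0, noise$jitter_sd))
    mid <- floor((b$start + b$end) / 2)
    s <- pmax(0L, pmin(as.integer(s), mid))
    e <- pmin(n_frames - 1L, pmax(as.integer(e), mid))
    lab <- integer(n_frames)
    for (i in seq_along(s)) lab[(s[i] + 1L):(e[i] + 1L)] <- 1L
  } else {
    lab <- integer(n_frames)
  }
  # spurious short bouts, kept clear of existing behavior so each remains a
  # distinct short bout
  n_false <- rpois(1, noise$false_rate * n_frames / 1000)
  for (k in seq_len(n_false)) {
    len <- sample(noise$false_len[1]:noise$false_len[2], 1L)
    for (try in 1:50) {
      s0 <- sample.int(n_frames - len + 1L, 1L)     # 1-based start
      lo <- max(1L, s0 - 2L); hi <- min(n_frames, s0 + len + 1L)
      if (all(lab[lo:hi] == 0L)) {
        lab[s0:(s0 + len - 1L)] <- 1L
        break
      }
    }
  }
  lab
}

#' Synthesize a pair of noisy annotator tracks
#'
#' Each track is the ground truth with bout boundaries dilated and jittered,
#' bouts dropped, and short false bouts inserted according to its noise
#' model. False bouts are placed clear of true behavior so they stay short
#' and separable.
#'
#' @param truth A `bout_list` of true bouts (or an `Ethogram`).
#' @param noise_a,noise_b [annotator_noise()] models for the two annotators.
#' @param n_frames Track length in frames.
#' @param seed Integer seed.
#' @param fps Frames per second for the output ethograms (default 30).
#' @return List of two `Ethogram`s `a` and `b`.
#' @export
synth_annotator_pair <- function(truth, noise_a, noise_b, n_frames, seed = 1,
                                 fps = 30) {
  if (inherits(truth, "Ethogram")) truth <- bouts_from_frames(truth)
  check_sorted_disjoint(truth)
  if (nrow(truth) && max(truth$end) > n_frames - 1L)
    stop("truth bouts exceed n_frames")
  set.seed(seed)
  la <- apply_annotator_noise(truth, noise_a, n_frames)
  lb <- apply_annotator_noise(truth, noise_b, n_frames)
  list(a = ethogram(la, fps = fps, source = "annotator_A"),
       b = ethogram(lb, fps = fps, source = "annotator_B"))
}

#' Synthesize a strain panel with known genetic architecture
#'
#' Inbred 0/1 genotypes per strain (optionally in LD blocks sharing a
#' founder haplotype), a genetic value built from `n_causal` SNPs scaled to
#' variance `h2`, and per-animal phenotypes with residual variance
#' `1 - h2`. Animals replicate their strain genotype; sexes alternate within
#' strain.
#'
#' @param n_strains Number of strains (default 60).
#' @param reps_per_strain Animals per strain (default 10).
#' @param n_snps Number of SNPs (default 500).
#' @param n_causal Number of causal SNPs (default 20; `<= n_snps`).
#' @param h2 Heritability, `0 <= h2 < 1` (default 0.5).
#' @param seed Integer seed.
#' @param n_chr Number of chromosomes the map is split into (default 1).
#' @param ld_block_size SNPs per LD block (default 1 = independent SNPs).
#' @param ld_mutation Per-SNP probability of flipping a strain's call away
#'   from its block founder haplotype (default 0.05; relevant when
#'   `ld_block_size > 1`).
#' @return List: `genotypes` (strain-level `GenotypeMatrix`),
#'   `animal_genotypes` (expanded to animals), `phenotypes` (a
#'   `PhenotypeTable` with one column `trait`), and `truth` (h2, causal SNP
#'   names, effects, strain genetic values).
#' @export
synth_panel <- function(n_strains = 60, reps_per_strain = 10, n_snps = 500,
                        n_causal = 20, h2 = 0.5, seed = 1, n_chr = 1,
                        ld_block_size = 1, ld_mutation = 0.05) {
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  if (n_causal > n_snps) stop("n_causal must be <= n_snps")
  set.seed(seed)
  G <- matrix(NA_real_, n_strains, n_snps)
  j <- 1L
  while (j <= n_snps) {
    width <- min(ld_block_size, n_snps - j + 1L)
    af <- runif(1, 0.15, 0.85)
    founder <- rbinom(n_strains, 1, af)
    for (b in seq_len(width)) {
      flip <- runif(n_strains) < ld_mutation
      G[, j + b - 1L] <- ifelse(flip, 1 - founder, founder)
    }
    j <- j + width
  }
  rownames(G) <- sprintf("strain%03d", seq_len(n_strains))
  chr <- as.character(rep_len(seq_len(n_chr), n_snps)[order(rep_len(seq_len(n_chr), n_snps))])
  map <- data.frame(snp = sprintf("snp%05d", seq_len(n_snps)),
                    chr = chr, pos = as.integer(stats::ave(seq_len(n_snps),
                                                           chr, FUN = seq_along)))
  colnames(G) <- map$snp
  geno <- genotype_matrix(G, map)

  causal <- sort(sample.int(n_snps, n_causal))
  beta <- rnorm(n_causal)
  gv <- as.numeric(G[, causal, drop = FALSE] %*% beta)
  if (h2 > 0 && sd(gv) > 0) {
    gv <- (gv - mean(gv)) / sd(gv) * sqrt(h2)
  } else {
    gv <- rep(0, n_strains)
  }
  n_animals <- n_strains * reps_per_strain
  strain_of <- rep(rownames(G), each = reps_per_strain)
  sexes <- rep_len(c("M", "F"), reps_per_strain)
  y <- gv[rep(seq_len(n_strains), each = reps_per_strain)] +
    rnorm(n_animals, 0, sqrt(1 - h2))
  pheno <- phenotype_table(animal = sprintf("animal%04d", seq_len(n_animals)),
                           strain = strain_of,
                           sex = rep(sexes, n_strains),
                           values = data.frame(trait = y))
  list(genotypes = geno,
       animal_genotypes = expand_genotypes(geno, strain_of),
       phenotypes = pheno,
       truth = list(h2 = h2, causal = map$snp[causal], beta = beta,
                    genetic_values = gv))
}
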