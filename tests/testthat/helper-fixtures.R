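# Shared fixtures: small cohorts and independent brute-force oracles.

small_cohort <- function(n_patients = 20, n_lesions = 26, seed = 7, ...) {
  generate_cohort(cohort_config(n_patients = n_patients,
                                n_lesions = n_lesions, seed = seed, ...))
}

# literal per-frame reimplementation of the geometric features, kept
# deliberately loop-based and independent of the package internals
oracle_geometric_features <- function(profile) {
  sp <- profile$frame_spacing
  seg_idx <- profile$segment_start:profile$segment_end
  les_idx <- profile$lesion_start:profile$lesion_end
  seg <- numeric(0)
  for (i in seg_idx) seg <- c(seg, profile$radii[i + 1])
  les <- numeric(0)
  for (i in les_idx) les <- c(les, profile$radii[i + 1])
  r_mean <- sum(seg) / length(seg)
  r_min <- seg[1]; r_max <- seg[1]
  for (r in seg) {
    if (r < r_min) r_min <- r
    if (r > r_max) r_max <- r
  }
  r_prox <- profile$radii[profile$lesion_start + 1]
  r_dist <- profile$radii[profile$lesion_end + 1]
  seg_len <- (profile$segment_end - profile$segment_start) * sp
  list(
    mean_lumen_radius = r_mean,
    minimum_lumen_radius = r_min,
    maximum_lumen_radius = r_max,
    mean_lumen_radius_stenosis = sum(les) / length(les),
    mean_radius_per_length = r_mean / seg_len,
    maximum_radius_rapport = (r_max - r_min) / r_max,
    stenosis_lesion_length = (profile$lesion_end - profile$lesion_start) * sp,
    percentage_diameter_reduction = 100 * (1 - 2 * r_mean / (r_prox + r_dist)),
    proximal_radius_rapport = (r_prox - r_dist) / r_prox,
    radius_rapport = ((r_prox + r_dist) / 2 - r_min) / ((r_prox + r_dist) / 2),
    proximal_area = pi * r_prox^2,
    distal_area = pi * r_dist^2
  )
}

random_profile <- function() {
  n <- sample(10:80, 1)
  radii <- runif(n, 0.3, 2.5)
  marks <- sort(sample(0:(n - 1), 4))
  if (marks[1] == marks[4]) marks[4] <- marks[1] + 1
  radii_profile(radii, segment_start = marks[1], lesion_start = marks[2],
                lesion_end = marks[3], segment_end = max(marks[4], marks[1] + 1),
                frame_spacing = sample(c(0.1, 0.2, 0.5), 1))
}

# O(n^2) pair-counting AUC oracle
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# exhaustive Se/Sp at a threshold (call positive when score >= t)
oracle_se_sp <- function(scores, labels, t) {
  c(se = sum(scores >= t & labels == 1) / sum(labels == 1),
    sp = sum(scores < t & labels == 0) / sum(labels == 0))
}

# brute-force closest-to-(0,1) scan over every candidate threshold
oracle_cutoff <- function(scores, labels) {
  u <- sort(unique(scores))
  cands <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best_t <- NA; best_d <- Inf; best_se <- -1
  for (t in cands) {
    ss <- oracle_se_sp(scores, labels, t)
    d <- sqrt((1 - ss["se"])^2 + (1 - ss["sp"])^2)
    better <- d < best_d - 1e-12 ||
      (abs(d - best_d) <= 1e-12 && ss["se"] > best_se + 1e-12) ||
      (abs(d - best_d) <= 1e-12 && abs(ss["se"] - best_se) <= 1e-12 && t < best_t)
    if (better) {
      best_t <- t; best_d <- d; best_se <- ss["se"]
    }
  }
  best_t
}
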