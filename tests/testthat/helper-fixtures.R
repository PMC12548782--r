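# Shared fixture builders and independent oracles.

noise_off <- c(poisson_scale = 0, gaussian_sd = 0)

quiet_spec <- function(...) {
  args <- list(...)
  defaults <- list(noise = noise_off, background = 300)
  do.call(field_spec, utils::modifyList(defaults, args))
}

# disk mask centred in an n x n matrix
disk_mask <- function(n, r, center = c((n + 1) / 2, (n + 1) / 2)) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= r^2
}

ellipse_mask <- function(n, a, b, center = c((n + 1) / 2, (n + 1) / 2)) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((rows - center[1]) / a)^2 + ((cols - center[2]) / b)^2 <= 1
}

# Independent brute-force 2D correlation with zero padding (no FFT): the
# oracle path for texture kernels.
conv2_oracle <- function(img, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  pr <- (kr - 1) %/% 2; pc <- (kc - 1) %/% 2
  pad <- matrix(0, nrow(img) + 2 * pr, ncol(img) + 2 * pc)
  pad[pr + seq_len(nrow(img)), pc + seq_len(ncol(img))] <- img
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    out <- out + kernel[i, j] *
      pad[(i - 1) + seq_len(nrow(img)), (j - 1) + seq_len(ncol(img))]
  }
  out
}

# Match segmented labels to ground-truth labels by maximal pixel overlap;
# returns per-truth-cell best Jaccard and the matched segmented label.
match_to_truth <- function(seg_labels, truth_labels) {
  seg <- as.matrix(seg_labels); tru <- as.matrix(truth_labels)
  n_t <- max(tru)
  out <- data.frame(truth = seq_len(n_t), seg = NA_integer_,
                    jaccard = 0)
  for (i in seq_len(n_t)) {
    tpx <- tru == i
    cand <- seg[tpx]; cand <- cand[cand > 0]
    if (!length(cand)) next
    s <- as.integer(names(which.max(table(cand))))
    spx <- seg == s
    out$seg[i] <- s
    out$jaccard[i] <- sum(tpx & spx) / sum(tpx | spx)
  }
  out
}

# Precision/recall of segmentation at a Jaccard threshold.
seg_pr <- function(seg_labels, truth_labels, j_min = 0.5) {
  m <- match_to_truth(seg_labels, truth_labels)
  tp <- sum(m$jaccard >= j_min)
  list(recall = tp / nrow(m), precision = tp / max(max(as.matrix(seg_labels)), 1),
       matches = m)
}

# Lazily generated, shared large fixtures (reused across test files).
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

field_50 <- function() cached_fixture("field_50", function()
  generate_field(quiet_spec(image_shape = c(1024, 1024), n_cells = 50,
                            cell_radius_range = c(28, 38),
                            er_peripheral_fraction = 0.4,
                            ridge_density = 3, hole_density = 3,
                            seed = 101)))

field_50_noisy <- function() cached_fixture("field_50_noisy", function()
  generate_field(quiet_spec(image_shape = c(1024, 1024), n_cells = 50,
                            cell_radius_range = c(28, 38),
                            er_peripheral_fraction = 0.4,
                            ridge_density = 3, hole_density = 3,
                            noise = c(poisson_scale = 4, gaussian_sd = 25),
                            seed = 102)))

# Closed-form pooled-variance two-sample t-test (independent oracle).
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# expansion-ratio recovery table for one simulated field run through the
# full segmentation + features path
recover_ratios <- function(sim, f_pn = 0.25, f_pe = 0.25) {
  nuc <- segment_nuclei(sim$field$channels$dna)
  cells <- segment_cells(nuc, sim$field$channels$cyto)
  qc <- qc_filter(cells, sim$field)
  feat <- compute_cell_features(sim$field, nuc, cells, qc,
                                f_pn = f_pn, f_pe = f_pe)
  m <- match_to_truth(cells, sim$truth$cell_labels)
  keep <- !is.na(m$seg)
  data.frame(truth_label = m$truth[keep],
             measured = feat$expansion_ratio[match(m$seg[keep], feat$label)],
             truth = sim$truth$cells$expansion_ratio[m$truth[keep]],
             jaccard = m$jaccard[keep],
             qc_pass = feat$qc_pass[match(m$seg[keep], feat$label)])
}
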