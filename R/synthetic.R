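## Synthetic-data generators with recorded ground truth.
##
## Every generator takes an explicit integer seed and is bit-reproducible.
## The returned objects carry the full truth needed to score downstream
## recovery (planted spot pairings, event frames, burst windows, target
## membership, parent sets).

#' Construct a spot field table
#'
#' A spot field is a data frame of subpixel spot coordinates with species,
#' cell and compartment labels, carrying the image frame size as attributes.
#' Coordinates follow the pixel-center convention: pixel `(i, j)` (0-based)
#' has its center at `x = j`, `y = i`, so valid coordinates span
#' `[0, width - 1]` and `[0, height - 1]`.
#'
#' @param x,y numeric subpixel coordinates (px).
#' @param species character species label (e.g. the probed RNA).
#' @param cell_id,compartment character labels; compartment is one of
#'   `"soma"`, `"neurite"`, `"other"`.
#' @param width,height image frame size in pixels.
#' @param spot_id integer spot identifiers (default sequential).
#' @return a `data.frame` of class `spot_field`.
#' @export
spot_field <- function(x, y, species = "rna", cell_id = "cell1",
                       compartment = "other", width, height,
                       spot_id = seq_along(x)) {
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(all(x >= 0 & x <= width - 1), "x out of frame")
  .assert(all(y >= 0 & y <= height - 1), "y out of frame")
  df <- data.frame(spot_id = as.integer(spot_id), x = as.numeric(x),
                   y = as.numeric(y), species = species, cell_id = cell_id,
                   compartment = compartment, stringsAsFactors = FALSE)
  attr(df, "width") <- as.integer(width)
  attr(df, "height") <- as.integer(height)
  class(df) <- c("spot_field", "data.frame")
  df
}

## resolve a mask_spec into a logical matrix: either a matrix directly, or
## list(width, height, coverage) giving a random mask with that area fraction
.resolve_mask_spec <- function(mask_spec) {
  if (is.matrix(mask_spec) || inherits(mask_spec, "structure_mask"))
    return(.as_mask_grid(mask_spec))
  .assert(is.list(mask_spec) && all(c("width", "height", "coverage") %in%
                                      names(mask_spec)),
          "mask_spec must be a binary matrix or list(width, height, coverage)")
  n <- mask_spec$height * mask_spec$width
  k <- round(mask_spec$coverage * n)
  g <- matrix(FALSE, mask_spec$height, mask_spec$width)
  g[sample.int(n, k)] <- TRUE
  g
}

#' Generate a spot field over a structure mask with a planted colocalized fraction
#'
#' Exactly `round(n_spots * coloc_fraction)` spots are placed at the centers of
#' uniformly sampled true-mask pixels plus isotropic Gaussian jitter of SD
#' `jitter_sd`; the remaining spots are uniform over the frame. Which spots
#' were planted on the structure is recorded in the returned truth.
#'
#' @param n_spots number of spots (>= 1).
#' @param mask_spec binary structure mask (matrix, `structure_mask`) or
#'   `list(width, height, coverage)` for a random mask.
#' @param coloc_fraction planted colocalized fraction in `[0, 1]`.
#' @param jitter_sd subpixel jitter SD in px.
#' @param seed integer seed.
#' @param soma_fraction fraction of spots labeled `"soma"` (rest `"neurite"`).
#' @return list of class `spot_field_truth` with elements `spots`
#'   (a [spot_field()]), `planted_coloc_fraction`, `jitter_sd`,
#'   `structure_mask` (logical matrix) and `is_coloc` (logical per spot).
#' @export
gen_spot_field <- function(n_spots, mask_spec, coloc_fraction, jitter_sd,
                           seed, soma_fraction = 0.5) {
  .assert(.is_count(n_spots), "n_spots must be a positive integer")
  .assert(coloc_fraction >= 0 && coloc_fraction <= 1,
          "coloc_fraction must be in [0, 1]")
  .assert(jitter_sd >= 0, "jitter_sd must be >= 0")
  set.seed(seed)
  grid <- .resolve_mask_spec(mask_spec)
  if (!any(grid)) stop("degenerate structure: mask has no true pixel")
  h <- nrow(grid); w <- ncol(grid)
  n_on <- round(n_spots * coloc_fraction)
  true_idx <- which(grid)
  on <- sample(true_idx, n_on, replace = TRUE)
  # 0-based pixel centers: row r, col c -> (x, y) = (c - 1, r - 1)
  x_on <- ((on - 1) %/% h) + rnorm(n_on, 0, jitter_sd)
  y_on <- ((on - 1) %% h) + rnorm(n_on, 0, jitter_sd)
  n_off <- n_spots - n_on
  x <- c(pmin(pmax(x_on, 0), w - 1), runif(n_off, 0, w - 1))
  y <- c(pmin(pmax(y_on, 0), h - 1), runif(n_off, 0, h - 1))
  comp <- sample(c("soma", "neurite"), n_spots, replace = TRUE,
                 prob = c(soma_fraction, 1 - soma_fraction))
  out <- list(
    spots = spot_field(x, y, compartment = comp, width = w, height = h),
    planted_coloc_fraction = coloc_fraction,
    jitter_sd = jitter_sd,
    structure_mask = grid,
    is_coloc = rep(c(TRUE, FALSE), c(n_on, n_off))
  )
  class(out) <- "spot_field_truth"
  out
}

#' Generate two spot fields with a planted mutual-colocalized fraction
#'
#' Emulates dual-color smFISH controls: a planted fraction of B spots
#' duplicates (with jitter) the position of a distinct A spot
#' (positive-control regime); `coloc_fraction = 0` gives fully independent
#' fields (negative-control regime).
#'
#' @param n_a,n_b spot counts of the two species (>= 1).
#' @param coloc_fraction fraction of B spots paired to an A spot; the implied
#'   number of pairs must not exceed `n_a`.
#' @param jitter_sd pairing jitter SD in px.
#' @param seed integer seed.
#' @param width,height frame size in pixels.
#' @return list of class `dual_spot_truth` with `a` and `b` ([spot_field()]s),
#'   `pairs` (data.frame `spot_a`, `spot_b` of planted pairings),
#'   `planted_coloc_fraction` and `jitter_sd`.
#' @export
gen_dual_spot_fields <- function(n_a, n_b, coloc_fraction, jitter_sd, seed,
                                 width = 256, height = 256) {
  .assert(.is_count(n_a) && .is_count(n_b), "n_a and n_b must be >= 1")
  .assert(coloc_fraction >= 0 && coloc_fraction <= 1,
          "coloc_fraction must be in [0, 1]")
  n_pair <- round(n_b * coloc_fraction)
  if (n_pair > n_a) stop("infeasible pairing: more paired B spots than A spots")
  set.seed(seed)
  ax <- runif(n_a, 0, width - 1); ay <- runif(n_a, 0, height - 1)
  partners <- sample.int(n_a, n_pair)
  bx <- c(ax[partners] + rnorm(n_pair, 0, jitter_sd),
          runif(n_b - n_pair, 0, width - 1))
  by <- c(ay[partners] + rnorm(n_pair, 0, jitter_sd),
          runif(n_b - n_pair, 0, height - 1))
  bx <- pmin(pmax(bx, 0), width - 1); by <- pmin(pmax(by, 0), height - 1)
  out <- list(
    a = spot_field(ax, ay, species = "A", width = width, height = height),
    b = spot_field(bx, by, species = "B", width = width, height = height),
    pairs = data.frame(spot_a = partners, spot_b = seq_len(n_pair)),
    planted_coloc_fraction = coloc_fraction,
    jitter_sd = jitter_sd
  )
  class(out) <- "dual_spot_truth"
  out
}

#' Generate per-synapse fluorescence traces with known release events
#'
#' Each trace is Gaussian baseline noise plus events with an instantaneous
#' rise of `amp_sd_units * noise_sd` and exponential decay with time constant
#' `decay_frames` (frames). Each field stimulus independently triggers an
#' evoked event in the frame after the stimulus frame with probability
#' `evoked_p`; spontaneous events arrive as a Poisson process at `spont_rate`.
#' The default stimulation protocol elsewhere in the package is 20 field
#' stimuli at 0.5 Hz imaged continuously at 20 Hz.
#'
#' @param n_synapses number of synapses.
#' @param frame_rate imaging rate, Hz.
#' @param duration_s recording length, s.
#' @param spont_rate spontaneous event rate per synapse, Hz.
#' @param evoked_p per-stimulus release probability in `[0, 1]`.
#' @param amp_sd_units event amplitude in multiples of the noise SD.
#' @param noise_sd baseline Gaussian noise SD (a.u.), > 0.
#' @param stim_times stimulus times in seconds (possibly empty).
#' @param decay_frames exponential decay time constant in frames.
#' @param seed integer seed.
#' @return list of class `trace_truth` with `traces` (a [trace_set()]),
#'   `events` (data.frame `synapse_id`, `frame`, `kind`), `stim_frames`,
#'   and the generator parameters.
#' @export
gen_release_traces <- function(n_synapses, frame_rate = 20, duration_s = 300,
                               spont_rate = 0, evoked_p = 0,
                               amp_sd_units = 10, noise_sd = 1,
                               stim_times = numeric(0), decay_frames = 2,
                               seed = 1) {
  .assert(frame_rate > 0, "frame_rate must be > 0")
  .assert(evoked_p >= 0 && evoked_p <= 1, "evoked_p must be in [0, 1]")
  .assert(noise_sd > 0, "noise_sd must be > 0")
  n_frames <- round(duration_s * frame_rate)
  stim_frames <- floor(stim_times * frame_rate) + 1L
  if (any(stim_frames + 1L > n_frames))
    stop("duration too short to contain stim_times")
  set.seed(seed)
  amp <- amp_sd_units * noise_sd
  values <- matrix(rnorm(n_synapses * n_frames, 0, noise_sd),
                   nrow = n_synapses)
  # event kernel: instantaneous rise, exponential decay
  klen <- min(n_frames, ceiling(8 * decay_frames) + 1L)
  kernel <- amp * exp(-(seq_len(klen) - 1) / decay_frames)
  ev <- vector("list", n_synapses)
  for (s in seq_len(n_synapses)) {
    evoked <- stim_frames[runif(length(stim_frames)) < evoked_p] + 1L
    n_sp <- rpois(1, spont_rate * duration_s)
    spont <- sample.int(n_frames, min(n_sp, n_frames))
    frames <- c(evoked, spont)
    kinds <- rep(c("evoked", "spontaneous"),
                 c(length(evoked), length(spont)))
    for (f in frames) {
      idx <- f:min(n_frames, f + klen - 1L)
      values[s, idx] <- values[s, idx] + kernel[seq_along(idx)]
    }
    if (length(frames))
      ev[[s]] <- data.frame(synapse_id = s, frame = frames, kind = kinds)
  }
  events <- do.call(rbind, ev)
  if (is.null(events))
    events <- data.frame(synapse_id = integer(0), frame = integer(0),
                         kind = character(0))
  out <- list(
    traces = trace_set(values, frame_rate = frame_rate,
                       stim_frames = stim_frames),
    events = events[order(events$synapse_id, events$frame), , drop = FALSE],
    stim_frames = stim_frames,
    spont_rate = spont_rate, evoked_p = evoked_p,
    amp_sd_units = amp_sd_units, noise_sd = noise_sd,
    decay_frames = decay_frames
  )
  class(out) <- "trace_truth"
  out
}

#' Generate multi-electrode spike trains with known burst structure
#'
#' Three synchrony regimes: `"identical"` copies one homogeneous Poisson
#' train to every electrode; `"independent_poisson"` draws i.i.d. trains;
#' `"network_bursting"` adds well-wide bursts (every electrode fires a burst
#' of `spikes_per_burst` spikes at `intra_isi_s` spacing, with per-electrode
#' onset jitter `N(0, jitter_s)`) on top of background Poisson firing.
#' Single-electrode bursts requested via `burst_spec` are placed at evenly
#' spaced offsets so inter-burst gaps are long relative to intra-burst ISIs.
#'
#' @param n_electrodes electrodes per well.
#' @param duration_s recording length, s.
#' @param mode one of `"independent_poisson"`, `"identical"`,
#'   `"network_bursting"`.
#' @param rate background firing rate per electrode, Hz (>= 0).
#' @param burst_spec optional `list(n_bursts, intra_isi_s, spikes_per_burst)`
#'   of planted single-electrode bursts (same layout on every electrode).
#' @param network_spec optional `list(n_net_bursts, jitter_s)`; used when
#'   `mode = "network_bursting"` (burst shape taken from `burst_spec`,
#'   default 6 spikes at 10 ms).
#' @param seed integer seed.
#' @param well_id well label.
#' @return list of class `spike_truth` with `trains` (a [spike_train_set()]),
#'   `true_bursts` (data.frame per planted single-electrode burst),
#'   `true_network_bursts` (data.frame of well-wide windows) and `sync_mode`.
#' @export
gen_spike_trains <- function(n_electrodes, duration_s, mode = "independent_poisson",
                             rate = 1, burst_spec = NULL, network_spec = NULL,
                             seed = 1, well_id = "well1") {
  .assert(rate >= 0, "rate must be >= 0")
  .assert(duration_s > 0, "duration_s must be > 0")
  mode <- match.arg(mode, c("independent_poisson", "identical",
                            "network_bursting"))
  set.seed(seed)
  pois_train <- function() sort(runif(rpois(1, rate * duration_s), 0, duration_s))
  trains <- switch(mode,
    identical = { tr <- pois_train(); replicate(n_electrodes, tr, simplify = FALSE) },
    independent_poisson = ,
    network_bursting = replicate(n_electrodes, pois_train(), simplify = FALSE))

  burst_len <- 0
  true_bursts <- NULL
  # in network_bursting mode burst_spec only sets the within-burst shape
  if (!is.null(burst_spec) && mode != "network_bursting") {
    nb <- burst_spec[[1]]; isi <- burst_spec[[2]]; k <- burst_spec[[3]]
    burst_len <- (k - 1) * isi
    if (nb * (burst_len + isi) > duration_s)
      stop("burst placement overflow: bursts do not fit in duration")
    slot <- duration_s / nb
    starts <- (seq_len(nb) - 0.5) * slot - burst_len / 2
    offs <- seq(0, by = isi, length.out = k)
    tb <- vector("list", n_electrodes)
    for (e in seq_len(n_electrodes)) {
      for (st in starts) trains[[e]] <- c(trains[[e]], st + offs)
      trains[[e]] <- sort(trains[[e]])
      tb[[e]] <- data.frame(electrode_id = e, start_s = starts,
                            end_s = starts + burst_len, n_spikes = k)
    }
    true_bursts <- do.call(rbind, tb)
  }

  true_network_bursts <- NULL
  if (mode == "network_bursting") {
    .assert(!is.null(network_spec), "network_spec required for network_bursting")
    nnb <- network_spec[[1]]; jit <- network_spec[[2]]
    isi <- if (!is.null(burst_spec)) burst_spec[[2]] else 0.01
    k <- if (!is.null(burst_spec)) burst_spec[[3]] else 6L
    blen <- (k - 1) * isi
    if (nnb * (blen + 6 * jit + isi) > duration_s)
      stop("burst placement overflow: network bursts do not fit in duration")
    slot <- duration_s / nnb
    starts <- (seq_len(nnb) - 0.5) * slot - blen / 2
    offs <- seq(0, by = isi, length.out = k)
    for (e in seq_len(n_electrodes)) {
      onset_jit <- rnorm(nnb, 0, jit)
      for (b in seq_len(nnb))
        trains[[e]] <- c(trains[[e]], starts[b] + onset_jit[b] + offs)
      trains[[e]] <- sort(pmin(pmax(trains[[e]], 0), duration_s))
    }
    true_network_bursts <- data.frame(well_id = well_id, start_s = starts,
                                      end_s = starts + blen)
  }

  df <- data.frame(
    well_id = well_id,
    electrode_id = rep(seq_len(n_electrodes), lengths(trains)),
    time_s = unlist(trains)
  )
  out <- list(
    trains = spike_train_set(df, duration_s = duration_s),
    true_bursts = true_bursts,
    true_network_bursts = true_network_bursts,
    sync_mode = mode
  )
  class(out) <- "spike_truth"
  out
}

#' Generate a count matrix with genotype/condition/batch structure
#'
#' Negative-binomial counts around per-gene lognormal baseline means.
#' Genes in `target_genes` are shifted by `planted_log2fc` in samples whose
#' `condition` is `"mir7_oex"`; per-(gene, batch) multiplicative effects with
#' log2 SD `batch_sd` are applied to all genes.
#'
#' @param n_genes number of genes.
#' @param design sample metadata data.frame with columns `genotype`,
#'   `condition` (values include `"mir7_oex"` for the shifted condition),
#'   `batch` and `animal`; one row per sample.
#' @param target_genes character subset of the generated gene ids
#'   (`gene0001`, ...).
#' @param planted_log2fc signed log2 effect on the target set.
#' @param dispersion negative-binomial dispersion (> 0); `size = 1/dispersion`.
#' @param batch_sd per-(gene, batch) log2 effect SD (0 disables).
#' @param seed integer seed.
#' @param baseline_meanlog,baseline_sdlog lognormal baseline parameters.
#' @return list of class `expression_truth` with `counts` (genes x samples
#'   integer matrix), `design`, `target_genes`, `planted_log2fc`,
#'   `batch_log2_effects` and `true_means`.
#' @export
gen_expression_counts <- function(n_genes, design, target_genes = character(0),
                                  planted_log2fc = 0, dispersion = 0.05,
                                  batch_sd = 0, seed = 1,
                                  baseline_meanlog = 5, baseline_sdlog = 1.2) {
  .assert(dispersion > 0, "dispersion must be > 0")
  .assert(all(c("genotype", "condition", "batch", "animal") %in% names(design)),
          "design needs genotype, condition, batch, animal columns")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  .assert(all(target_genes %in% genes),
          "target_genes must be a subset of the generated gene ids")
  n_s <- nrow(design)
  base <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  mu <- matrix(base, n_genes, n_s)
  is_t <- genes %in% target_genes
  oex <- design$condition == "mir7_oex"
  mu[is_t, oex] <- mu[is_t, oex] * 2^planted_log2fc
  batches <- unique(design$batch)
  beff <- matrix(0, n_genes, length(batches), dimnames = list(genes, batches))
  if (batch_sd > 0) {
    beff[] <- rnorm(n_genes * length(batches), 0, batch_sd)
    mu <- mu * 2^beff[, as.character(design$batch), drop = FALSE]
  }
  counts <- matrix(rnbinom(n_genes * n_s, mu = mu, size = 1 / dispersion),
                   n_genes, n_s,
                   dimnames = list(genes, rownames(design) %||%
                                     paste0("sample", seq_len(n_s))))
  out <- list(counts = counts, design = design, target_genes = target_genes,
              planted_log2fc = planted_log2fc, batch_log2_effects = beff,
              true_means = mu)
  class(out) <- "expression_truth"
  out
}

#' Construct a tiered gene regulatory network
#'
#' @param nodes data.frame with columns `gene` and `role` (one of
#'   `"phenotype"`, `"intermediate"`, `"mir7_target"`, `"decoy"`).
#' @param edges data.frame with columns `from` (parent/regulator), `to`
#'   (child/response) and `weight`; edges must point mir7_target ->
#'   intermediate or intermediate -> phenotype.
#' @return list of class `gene_network`.
#' @export
gene_network <- function(nodes, edges) {
  .assert(all(c("gene", "role") %in% names(nodes)), "nodes needs gene, role")
  .assert(all(c("from", "to", "weight") %in% names(edges)),
          "edges needs from, to, weight")
  role <- setNames(nodes$role, nodes$gene)
  ok <- (role[edges$from] == "mir7_target" & role[edges$to] == "intermediate") |
        (role[edges$from] == "intermediate" & role[edges$to] == "phenotype")
  if (!all(ok)) stop("cyclic or ill-tiered network: edges must point mir7_target -> intermediate -> phenotype")
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' Plant a two-tier regulatory network
#'
#' Builds a [gene_network()] with a recoverable overlap structure. Driving
#' miR-7 targets come in pairs, each pair regulating a pair of
#' intermediates through orthogonal weight vectors
#' (`im_a = w1 t1 + w2 t2`, `im_b = w2 t1 - w1 t2`): every driving target
#' regulates exactly two intermediates (so the top-k overlap rule can
#' recover it), yet all intermediates are mutually uncorrelated, which
#' keeps spurious cross-edges at the chance level. The remaining targets
#' carry no out-edges (database-listed but inert). The phenotype tier mirrors
#' the construction: phenotype pairs sit on disjoint intermediate pairs with
#' orthogonal weights, so every intermediate drives exactly two phenotype
#' genes and the phenotype responses are mutually uncorrelated as well.
#'
#' @param n_phenotype number of phenotype-related genes; must equal
#'   `n_intermediate` (the tiers pair up one-to-one).
#' @param n_intermediate even number of intermediate regulators (>= 4).
#' @param n_targets size of the miR-7 target tier (>= `n_intermediate`
#'   driving targets).
#' @param weight_range absolute edge weights drawn uniformly from this range
#'   with random sign.
#' @param seed integer seed.
#' @return a [gene_network()].
#' @export
plant_two_tier_network <- function(n_phenotype = 8, n_intermediate = 8,
                                   n_targets = 600,
                                   weight_range = c(0.9, 1), seed = 1) {
  .assert(n_intermediate >= 4 && n_intermediate %% 2 == 0,
          "n_intermediate must be even and >= 4")
  .assert(n_targets >= n_intermediate, "n_targets smaller than the driving set")
  .assert(n_phenotype == n_intermediate,
          "the tiers pair up one-to-one: n_phenotype must equal n_intermediate")
  set.seed(seed)
  ph <- sprintf("pheno%02d", seq_len(n_phenotype))
  im <- sprintf("reg%02d", seq_len(n_intermediate))
  tg <- sprintf("target%04d", seq_len(n_targets))
  nodes <- data.frame(
    gene = c(ph, im, tg),
    role = rep(c("phenotype", "intermediate", "mir7_target"),
               c(n_phenotype, n_intermediate, n_targets))
  )
  rw <- function(n) sample(c(-1, 1), n, TRUE) * runif(n, weight_range[1],
                                                      weight_range[2])
  # step-2 edges: orthogonal-pair blocks
  e2 <- vector("list", n_intermediate / 2)
  for (k in seq_len(n_intermediate / 2)) {
    t1 <- tg[2 * k - 1]; t2 <- tg[2 * k]
    ia <- im[2 * k - 1]; ib <- im[2 * k]
    w <- rw(2)
    e2[[k]] <- data.frame(from = c(t1, t2, t1, t2),
                          to = c(ia, ia, ib, ib),
                          weight = c(w[1], w[2], w[2], -w[1]), step = 2L)
  }
  # step-1 edges: phenotype pairs on disjoint intermediate pairs, again with
  # orthogonal weight vectors
  e1 <- vector("list", n_intermediate / 2)
  for (k in seq_len(n_intermediate / 2)) {
    ia <- im[2 * k - 1]; ib <- im[2 * k]
    pa <- ph[2 * k - 1]; pb <- ph[2 * k]
    u <- rw(2)
    e1[[k]] <- data.frame(from = c(ia, ib, ia, ib),
                          to = c(pa, pa, pb, pb),
                          weight = c(u[1], u[2], u[2], -u[1]), step = 1L)
  }
  gene_network(nodes, rbind(do.call(rbind, e2), do.call(rbind, e1)))
}

#' Simulate expression data from a planted regulatory network
#'
#' Root-tier genes (miR-7 targets) are drawn i.i.d. standard normal; each
#' child gene is the weighted sum of its parents plus `N(0, noise_sd)`;
#' decoy genes are independent standard normal.
#'
#' @param network a [gene_network()].
#' @param n_samples number of samples (columns).
#' @param n_decoy_genes independent noise genes appended to the matrix.
#' @param noise_sd additive child noise SD (>= 0).
#' @param seed integer seed.
#' @return list of class `expression_truth` with `counts` (genes x samples
#'   numeric abundances), `network` and `target_genes`.
#' @export
gen_regulatory_expression <- function(network, n_samples, n_decoy_genes = 0,
                                      noise_sd = 0.1, seed = 1) {
  .assert(inherits(network, "gene_network"), "network must be a gene_network")
  .assert(noise_sd >= 0, "noise_sd must be >= 0")
  set.seed(seed)
  nodes <- network$nodes; edges <- network$edges
  expr <- matrix(NA_real_, nrow(nodes), n_samples,
                 dimnames = list(nodes$gene, paste0("s", seq_len(n_samples))))
  roots <- nodes$gene[nodes$role == "mir7_target"]
  expr[roots, ] <- rnorm(length(roots) * n_samples)
  for (tier in c("intermediate", "phenotype")) {
    for (g in nodes$gene[nodes$role == tier]) {
      pe <- edges[edges$to == g, , drop = FALSE]
      val <- if (nrow(pe)) {
        colSums(expr[pe$from, , drop = FALSE] * pe$weight)
      } else rep(0, n_samples)
      expr[g, ] <- val + if (noise_sd > 0) rnorm(n_samples, 0, noise_sd) else 0
    }
  }
  if (n_decoy_genes > 0) {
    dec <- matrix(rnorm(n_decoy_genes * n_samples), n_decoy_genes, n_samples,
                  dimnames = list(sprintf("decoy%04d", seq_len(n_decoy_genes)),
                                  colnames(expr)))
    expr <- rbind(expr, dec)
  }
  out <- list(counts = expr, network = network,
              target_genes = nodes$gene[nodes$role == "mir7_target"])
  class(out) <- "expression_truth"
  out
}
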