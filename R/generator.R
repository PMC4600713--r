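#' Parameters for the synthetic connectome generator
#'
#' The generator emulates the statistical structure of streamline-count
#' structural brain networks: sparse, symmetric, zero-diagonal matrices
#' with positive integer weights, modular block structure, a minority of
#' high-strength hub regions forming a rich-club core that bridges
#' communities, and mild scan-to-scan measurement noise.
#'
#' The model is a degree-corrected weighted stochastic block model. Every
#' region carries a log-normal propensity `s_i` (the analogue of regional
#' seed volume in tractography: large regions accumulate more and stronger
#' streamlines). Edge presence within a community follows
#' `min(1, p_within * theta_i * theta_j)` with `theta` the mean-normalized
#' propensity; between communities a fraction `between_gateway_frac` of
#' `p_between` is propensity-independent (long-range tracts exist where
#' anatomy provides a pathway, regardless of regional size) and the rest is
#' degree-corrected. Edge weights are `round(lognormal * s_i * s_j)`,
#' clamped at 1. Hub regions (spread round-robin over communities) have
#' their propensity multiplied by `hub_boost`, receive extra
#' between-community attachment, and are near-fully interconnected
#' (`hub_rich_p`), forming the rich-club backbone that integrates the
#' modules.
#'
#' Defaults describe a 234-region network with eight communities at about
#' 8% overall density, median edge weight around 7 streamlines with a
#' heavy right tail, and 12 hubs boosted threefold.
#'
#' @param n_regions number of regions (default 234).
#' @param n_communities number of modules.
#' @param p_within,p_between within/between-community base edge
#'   probabilities; `p_between < p_within` is required (modular structure).
#' @param between_gateway_frac fraction of `p_between` that is
#'   propensity-independent, in `[0, 1]`.
#' @param weight_law `"rounded_lognormal"` (positive integers, minimum 1 on
#'   existing edges; the default, matching streamline counts) or
#'   `"lognormal"` (continuous positive weights, useful for
#'   generic-controllability checks, where integer ties are undesirable).
#' @param weight_meanlog,weight_sdlog log-normal weight noise parameters.
#' @param prop_sd standard deviation (log scale) of the regional propensity
#'   `s_i`; 0 disables degree correction (plain block model).
#' @param n_hubs number of hub regions.
#' @param hub_boost multiplicative propensity factor (>= 1) for hubs: all
#'   hub-incident weights scale by it in expectation.
#' @param hub_p_extra extra between-community attachment probability
#'   (degree-corrected) for hub-incident pairs.
#' @param hub_rich_p minimum presence probability of hub-hub edges (the
#'   rich club).
#' @param scan_noise fraction in `[0, 1)`: calibrated so that the mean
#'   relative weight difference between two scans of one subject, over
#'   edges present in both, is approximately `scan_noise`.
#' @param edge_flip fraction of edges resampled (deleted and replaced
#'   elsewhere) between scans; applied only when `scan_noise > 0`.
#' @param seed master integer seed; all per-subject and per-scan random
#'   streams derive from it deterministically.
#' @return a `generator_params` list, validated.
#' @export
generator_params <- function(n_regions = 234, n_communities = 8,
                             p_within = 0.6, p_between = 0.01,
                             between_gateway_frac = 0.4,
                             weight_law = c("rounded_lognormal", "lognormal"),
                             weight_meanlog = 2, weight_sdlog = 0.5,
                             prop_sd = 0.7,
                             n_hubs = 12, hub_boost = 3, hub_p_extra = 0.02,
                             hub_rich_p = 0.9,
                             scan_noise = 0.1, edge_flip = 0.02, seed = 1) {
  weight_law <- match.arg(weight_law)
  p <- list(n_regions = as.integer(n_regions),
            n_communities = as.integer(n_communities),
            p_within = p_within, p_between = p_between,
            between_gateway_frac = between_gateway_frac,
            weight_law = weight_law,
            weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
            prop_sd = prop_sd,
            n_hubs = as.integer(n_hubs), hub_boost = hub_boost,
            hub_p_extra = hub_p_extra, hub_rich_p = hub_rich_p,
            scan_noise = scan_noise, edge_flip = edge_flip,
            seed = as.integer(seed))
  if (p$n_regions < 1) stop("n_regions must be positive")
  if (p$n_communities < 1 || p$n_communities > p$n_regions)
    stop("n_communities must be in 1..n_regions")
  probs <- c(p$p_within, p$p_between, p$hub_p_extra, p$hub_rich_p,
             p$between_gateway_frac)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (p$p_between > p$p_within)
    stop("modular structure requires p_between <= p_within")
  if (p$n_hubs < 0 || p$n_hubs > p$n_regions)
    stop("n_hubs must be in 0..n_regions")
  if (p$hub_boost < 1) stop("hub_boost must be >= 1")
  if (p$prop_sd < 0) stop("prop_sd must be >= 0")
  if (p$scan_noise < 0 || p$scan_noise >= 1) stop("scan_noise in [0, 1)")
  if (p$edge_flip < 0 || p$edge_flip > 1) stop("edge_flip in [0, 1]")
  class(p) <- "generator_params"
  p
}

# Deterministic sub-seed streams from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

# Log-normal weight noise; integer law rounds with a floor of 1.
finalize_weights <- function(raw, params) {
  if (params$weight_law == "rounded_lognormal") pmax(1, round(raw)) else raw
}

#' Generate one synthetic connectome
#'
#' Draws one network from the degree-corrected weighted block model
#' described in [generator_params]. Output is always symmetric,
#' zero-diagonal and nonnegative (positive integers under the default
#' weight law); identical seeds give identical matrices. The designated hub
#' regions and the community assignment are recorded as attributes `hubs`
#' and `communities`.
#'
#' @param params a [generator_params] object.
#' @param subject,scan optional tags recorded on the connectome.
#' @param seed optional seed overriding `params$seed` (used by
#'   [generate_cohort] to drive per-subject streams).
#' @return a [connectome].
#' @export
generate_connectome <- function(params = generator_params(),
                                subject = NA_character_,
                                scan = NA_character_, seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_regions
  set.seed(if (is.null(seed)) params$seed else seed)
  comm <- sort(rep(seq_len(params$n_communities), length.out = n))
  s <- exp(stats::rnorm(n, 0, params$prop_sd))
  hubs <- integer(0)
  if (params$n_hubs > 0) {
    # spread hubs across communities round-robin
    by_comm <- lapply(split(seq_len(n), comm), sample)
    rr <- unlist(lapply(seq_len(max(lengths(by_comm))), function(k)
      unlist(lapply(by_comm, function(v) if (k <= length(v)) v[k]))))
    hubs <- sort(rr[seq_len(params$n_hubs)])
    s[hubs] <- s[hubs] * params$hub_boost
  }
  idx <- which(upper.tri(matrix(0, n, n)))
  ri <- row(matrix(0, n, n))[idx]
  ci <- col(matrix(0, n, n))[idx]
  theta <- s / exp(params$prop_sd^2 / 2)   # mean-normalized propensity
  tt <- theta[ri] * theta[ci]
  within <- comm[ri] == comm[ci]
  pb0 <- params$between_gateway_frac * params$p_between
  pbdc <- params$p_between - pb0
  p <- ifelse(within,
              pmin(1, params$p_within * tt),
              pmin(1, pb0 + pbdc * tt))
  if (length(hubs) > 0) {
    is_hub_pair <- (ri %in% hubs) | (ci %in% hubs)
    both_hub <- (ri %in% hubs) & (ci %in% hubs)
    p <- ifelse(!within & is_hub_pair,
                pmin(1, pb0 + (pbdc + params$hub_p_extra) * tt), p)
    p <- ifelse(both_hub, pmax(p, params$hub_rich_p), p)
  }
  present <- stats::runif(length(idx)) < p
  A <- matrix(0, n, n)
  m <- sum(present)
  if (m > 0) {
    raw <- exp(stats::rnorm(m, params$weight_meanlog, params$weight_sdlog)) *
      (s[ri] * s[ci])[present]
    A[idx[present]] <- finalize_weights(raw, params)
  }
  A <- A + t(A)
  conn <- connectome(A, subject = subject, scan = scan)
  attr(conn, "hubs") <- conn$regions[hubs]
  attr(conn, "communities") <- stats::setNames(comm, conn$regions)
  conn
}

# Apply scan-to-scan noise to a subject-template connectome: multiplicative
# log-normal weight jitter (sdlog calibrated so the expected relative
# difference between two independently jittered scans is ~ scan_noise) plus
# resampling of a small fraction of edges. Symmetry/integrality preserved.
perturb_scan <- function(template, params, seed, scan = NA_character_) {
  if (params$scan_noise == 0) {
    out <- template
    out$scan <- as.character(scan)
    return(out)
  }
  set.seed(seed)
  A <- template$A
  ut <- which(upper.tri(A))
  w <- A[ut]
  on_edges <- which(w > 0)
  # |f1 - f2| for two iid lognormal(0, s) factors has mean ~ 2s/sqrt(pi)
  s <- params$scan_noise * sqrt(pi) / 2
  jit <- w[on_edges] * exp(stats::rnorm(length(on_edges), 0, s))
  w[on_edges] <- finalize_weights(jit, params)
  n_flip <- round(params$edge_flip * length(on_edges))
  if (n_flip > 0 && length(on_edges) > n_flip) {
    off_edges <- which(w == 0)
    drop_idx <- sample(on_edges, n_flip)
    add_idx <- sample(off_edges, min(n_flip, length(off_edges)))
    w[drop_idx] <- 0
    mu <- params$weight_meanlog
    w[add_idx] <- finalize_weights(
      exp(stats::rnorm(length(add_idx), mu, params$weight_sdlog)), params)
  }
  A[ut] <- w
  A[lower.tri(A)] <- 0
  A <- A + t(A)
  out <- connectome(A, regions = template$regions,
                    subject = template$subject, scan = scan)
  attr(out, "hubs") <- attr(template, "hubs")
  attr(out, "communities") <- attr(template, "communities")
  out
}

#' Generate a cohort of synthetic connectomes
#'
#' Each subject gets a template network drawn from the block model; each of
#' its scans is an independently noise-perturbed copy of that template
#' (weight jitter + edge resampling controlled by `scan_noise` and
#' `edge_flip`). With `scan_noise = 0` all scans of a subject are
#' identical. All randomness derives from the master seed in `params`.
#'
#' @param params a [generator_params] object.
#' @param n_subjects,n_scans cohort design (defaults 8 subjects in
#'   triplicate, the standard test-retest design for this analysis).
#' @return list of `n_subjects * n_scans` [connectome]s, tagged
#'   `subject = "S1".."Sn"`, `scan = "1".."k"`, ordered subject-major.
#' @export
generate_cohort <- function(params = generator_params(), n_subjects = 8,
                            n_scans = 3) {
  stopifnot(inherits(params, "generator_params"))
  n_subjects <- as.integer(n_subjects)
  n_scans <- as.integer(n_scans)
  if (n_subjects < 1 || n_scans < 1) stop("n_subjects and n_scans must be >= 1")
  seeds <- matrix(derive_seeds(params$seed, n_subjects * (n_scans + 1)),
                  n_subjects, n_scans + 1)
  out <- vector("list", n_subjects * n_scans)
  idx <- 1
  for (s in seq_len(n_subjects)) {
    template <- generate_connectome(params, subject = sprintf("S%d", s),
                                    seed = seeds[s, 1])
    for (r in seq_len(n_scans)) {
      out[[idx]] <- perturb_scan(template, params, seeds[s, r + 1],
                                 scan = as.character(r))
      idx <- idx + 1
    }
  }
  out
}

#' Canonical cognitive system names
#'
#' The eight resting-state cognitive systems used to label regions.
#' @return character vector of length 8.
#' @export
cognitive_systems <- function() {
  c("auditory", "visual", "sensorimotor", "ventral_attention",
    "dorsal_attention", "default_mode", "frontoparietal",
    "cingulo_opercular")
}

#' Generate region-to-cognitive-system labels
#'
#' Assigns every region to one of the eight cognitive systems. Each system
#' is guaranteed non-empty; remaining regions are assigned with
#' probabilities loosely reflecting relative system sizes in cortical
#' parcellations (default mode and sensorimotor largest, auditory
#' smallest).
#'
#' @param n_regions number of regions (>= 8).
#' @param seed integer seed.
#' @param regions optional region id vector (defaults to `R001..`).
#' @return data.frame with columns `region_id`, `system`.
#' @export
generate_system_labels <- function(n_regions, seed = 1, regions = NULL) {
  n_regions <- as.integer(n_regions)
  systems <- cognitive_systems()
  if (n_regions < length(systems))
    stop("need at least ", length(systems), " regions to cover all systems")
  if (is.null(regions)) regions <- sprintf("R%03d", seq_len(n_regions))
  stopifnot(length(regions) == n_regions)
  set.seed(seed)
  prob <- c(auditory = 0.05, visual = 0.14, sensorimotor = 0.17,
            ventral_attention = 0.08, dorsal_attention = 0.08,
            default_mode = 0.25, frontoparietal = 0.12,
            cingulo_opercular = 0.11)
  lab <- c(systems,
           sample(systems, n_regions - length(systems), replace = TRUE,
                  prob = prob[systems]))
  lab <- sample(lab)   # shuffle so the guaranteed ones are not positional
  data.frame(region_id = regions, system = lab, stringsAsFactors = FALSE)
}
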