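# Seeded synthetic-data generators with known ground truth for every
# pipeline stage.  Each generator seeds the RNG explicitly, returns the
# generated data together with a `ground_truth` manifest, and regenerates
# identical output for identical seeds.

.ground_truth <- function(generator, seed, params) {
  structure(list(generator = generator, seed = seed, params = params),
            class = "ground_truth")
}

#' Synthetic authigenic ratio series at known true ages
#'
#' Inverts the decay law: each sample's ratio is
#' `n0 * exp(-lambda * age) * (1 + eps)` with multiplicative Gaussian noise,
#' and the reported 1-sigma equals `rel_noise * ratio`.
#'
#' @param true_ages True depositional ages, Ma (>= 0).
#' @param n0 True initial ratio (dimensionless, unscaled).
#' @param rel_noise Relative noise SD (default 0.02).
#' @param seed Integer seed.
#' @param decay A [decay_model()].
#' @return List: `data` (data frame `sample_id`, `role`, `context`, `ratio`,
#'   `sigma`) and `truth` (a `ground_truth` manifest).
#' @export
gen_ratio_series <- function(true_ages, n0, rel_noise = 0.02, seed = 1L,
                             decay = decay_model()) {
  if (any(true_ages < 0)) stop_invalid("true ages must be >= 0")
  set.seed(seed)
  clean <- ratio_at_age(true_ages, initial_ratio(n0), decay)
  ratio <- clean * (1 + stats::rnorm(length(true_ages), 0, rel_noise))
  d <- data.frame(sample_id = sprintf("SYN-%03d", seq_along(true_ages)),
                  role = "fossil", context = "other",
                  ratio = ratio, sigma = rel_noise * ratio,
                  stringsAsFactors = FALSE)
  list(data = d,
       truth = .ground_truth("gen_ratio_series", seed,
                             list(true_ages = true_ages, n0 = n0,
                                  rel_noise = rel_noise,
                                  half_life = decay$half_life)))
}

#' Synthetic quartz concentration pairs from the forward burial model
#'
#' @param t True burial duration, Ma.
#' @param eps_pre Pre-burial denudation, m Ma^-1.
#' @param depth Sampling depth, m (`NULL` for the no-post-burial model).
#' @param eps_post Post-burial denudation, m Ma^-1.
#' @param system,site As in [forward_burial()].
#' @param rel_noise Relative (multiplicative Gaussian) noise SD.
#' @param seed Integer seed.
#' @param n Number of replicate samples (default 1).
#' @return List: `data` (data frame `sample_id`, `depth_m`, `n_be`,
#'   `n_be_sigma`, `n_al`, `n_al_sigma`) and `truth`.
#' @export
gen_burial_samples <- function(t, eps_pre, system, site, depth = NULL,
                               eps_post = 0, rel_noise = 0, seed = 1L,
                               n = 1L) {
  set.seed(seed)
  clean <- forward_burial(t, eps_pre, system, site, depth = depth,
                          eps_post = eps_post)
  rows <- lapply(seq_len(n), function(i) {
    nb <- clean["be10"] * (1 + stats::rnorm(1, 0, rel_noise))
    na_ <- clean["al26"] * (1 + stats::rnorm(1, 0, rel_noise))
    data.frame(sample_id = sprintf("QTZ-%03d", i),
               depth_m = depth %||% NA_real_,
               n_be = unname(nb), n_be_sigma = rel_noise * unname(nb),
               n_al = unname(na_), n_al_sigma = rel_noise * unname(na_))
  })
  list(data = do.call(rbind, rows),
       truth = .ground_truth("gen_burial_samples", seed,
                             list(t = t, eps_pre = eps_pre, depth = depth,
                                  eps_post = eps_post,
                                  rel_noise = rel_noise)))
}

#' Synthetic pedogenic-carbonate table
#'
#' Bivariate normal (delta-13C, delta-18O) with a target correlation;
#' heights are equally spaced from the section base; carbonate content is
#' uniform in a plausible range.
#'
#' @param n Number of nodules (>= 3).
#' @param mean13,sd13 delta-13C moments (per mil).
#' @param mean18,sd18 delta-18O moments (per mil).
#' @param rho Target correlation, |rho| < 1.
#' @param seed Integer seed.
#' @return List: `data` (layout of [mazamba_carbonates()]) and `truth`.
#' @export
gen_carbonate_table <- function(n = 17L, mean13 = -7.3, sd13 = 1.0,
                                mean18 = 25.9, sd18 = 0.3, rho = 0.3,
                                seed = 1L) {
  if (n < 3L) stop_invalid("n must be >= 3")
  if (abs(rho) >= 1) stop_invalid("|rho| must be < 1")
  set.seed(seed)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  d13 <- mean13 + sd13 * z1
  d18 <- mean18 + sd18 * (rho * z1 + sqrt(1 - rho^2) * z2)
  d <- data.frame(sample_id = sprintf("SYN-CARB-%03d", seq_len(n)),
                  height_cm = seq(10, by = 20, length.out = n),
                  d13c_vpdb = d13, d18o_vsmow = d18,
                  powder_mass_ug = round(stats::runif(n, 110, 370)),
                  carbonate_pct = round(stats::runif(n, 50, 98)),
                  stringsAsFactors = FALSE)
  list(data = d,
       truth = .ground_truth("gen_carbonate_table", seed,
                             list(n = n, mean13 = mean13, sd13 = sd13,
                                  mean18 = mean18, sd18 = sd18, rho = rho)))
}

#' Synthetic labelled outline classes from harmonic templates
#'
#' Each specimen perturbs its class template's elliptical Fourier
#' coefficients with Gaussian noise and reconstructs an outline through
#' [inverse_eft()]; optionally the outline is rasterized into a filled
#' binary image for the tracing pipeline.
#'
#' @param templates Named list of coefficient sets (each a list with `an`,
#'   `bn`, `cn`, `dn` and optional `a0`, `c0`); >= 2 classes.
#' @param n_per_class Specimens per class.
#' @param coef_sd SD of the coefficient perturbation.
#' @param k Points per outline (default 100).
#' @param seed Integer seed.
#' @param raster Also return filled binary rasters (default `FALSE`).
#' @param img_size Raster side length in pixels (default 400).
#' @return List: `outlines` (list of k x 2 matrices), `labels`, optional
#'   `images`, and `truth`.
#' @export
gen_outline_classes <- function(templates, n_per_class = 20L, coef_sd = 0.01,
                                k = 100L, seed = 1L, raster = FALSE,
                                img_size = 400L) {
  if (length(templates) < 2L) stop_invalid("need at least 2 class templates")
  if (is.null(names(templates)))
    names(templates) <- paste0("class", seq_along(templates))
  set.seed(seed)
  outlines <- list()
  labels <- character(0)
  images <- if (raster) list() else NULL
  for (cl in names(templates)) {
    tp <- templates[[cl]]
    for (i in seq_len(n_per_class)) {
      nz <- length(tp$an)
      co <- list(an = tp$an + stats::rnorm(nz, 0, coef_sd),
                 bn = tp$bn + stats::rnorm(nz, 0, coef_sd),
                 cn = tp$cn + stats::rnorm(nz, 0, coef_sd),
                 dn = tp$dn + stats::rnorm(nz, 0, coef_sd),
                 a0 = tp$a0 %||% 0, c0 = tp$c0 %||% 0)
      o <- inverse_eft(co, k)
      outlines[[length(outlines) + 1L]] <- o
      labels <- c(labels, cl)
      if (raster)
        images[[length(images) + 1L]] <- rasterize_outline(o, img_size)
    }
  }
  out <- list(outlines = outlines, labels = labels,
              truth = .ground_truth("gen_outline_classes", seed,
                                    list(classes = names(templates),
                                         n_per_class = n_per_class,
                                         coef_sd = coef_sd, k = k)))
  if (raster) out$images <- images
  out
}

#' Rasterize a closed outline into a filled binary image
#'
#' The outline is scaled into the image with a margin and filled by
#' even-odd polygon scan conversion.
#'
#' @param outline k x 2 matrix.
#' @param img_size Side length in pixels.
#' @param margin Fractional margin (default 0.1).
#' @return `img_size` x `img_size` binary matrix (1 = foreground).
#' @export
rasterize_outline <- function(outline, img_size = 400L, margin = 0.1) {
  rng_x <- range(outline[, 1L]); rng_y <- range(outline[, 2L])
  span <- max(diff(rng_x), diff(rng_y))
  if (span <= 0) stop_invalid("degenerate outline")
  scale <- img_size * (1 - 2 * margin) / span
  px <- (outline[, 1L] - mean(rng_x)) * scale + img_size / 2
  py <- (outline[, 2L] - mean(rng_y)) * scale + img_size / 2
  img <- matrix(0, img_size, img_size)
  # scanline fill, even-odd rule; image row r corresponds to y = size+1-r
  xs <- px; ys <- py
  nseg <- length(xs)
  x2 <- xs[c(2:nseg, 1L)]; y2 <- ys[c(2:nseg, 1L)]
  for (r in seq_len(img_size)) {
    yy <- img_size + 1L - r
    cross <- ((ys <= yy) & (y2 > yy)) | ((y2 <= yy) & (ys > yy))
    if (!any(cross)) next
    xi <- xs[cross] + (yy - ys[cross]) / (y2[cross] - ys[cross]) *
      (x2[cross] - xs[cross])
    xi <- sort(xi)
    for (j in seq(1L, length(xi) - 1L, by = 2L)) {
      c1 <- max(1L, ceiling(xi[j])); c2 <- min(img_size, floor(xi[j + 1L]))
      if (c1 <= c2) img[r, c1:c2] <- 1
    }
  }
  img
}

#' Synthetic 3D semilandmark configurations with tangential noise
#'
#' Perturbs a base configuration along each curve's local tangent (noise
#' that sliding can remove) plus a smaller isotropic component.
#'
#' @param base k x 3 base coordinate matrix.
#' @param scheme A [semilandmark_scheme()].
#' @param tangent_sd SD of along-tangent noise.
#' @param iso_sd SD of isotropic noise (default `tangent_sd / 20`).
#' @param n Number of configurations.
#' @param seed Integer seed.
#' @return List: `configs` (list of k x 3 matrices) and `truth`.
#' @export
gen_configurations3d <- function(base, scheme, tangent_sd = 0.02,
                                 iso_sd = tangent_sd / 20, n = 10L,
                                 seed = 1L) {
  stopifnot(inherits(scheme, "semilandmark_scheme"))
  set.seed(seed)
  configs <- lapply(seq_len(n), function(i) {
    s <- base
    for (cv in scheme$curves) {
      m <- length(cv)
      for (jj in seq_len(m)) {
        idx <- cv[jj]
        if (idx %in% scheme$fixed) next
        tangent <- base[cv[min(jj + 1L, m)], ] - base[cv[max(jj - 1L, 1L)], ]
        tangent <- tangent / sqrt(sum(tangent^2))
        s[idx, ] <- s[idx, ] + tangent * stats::rnorm(1, 0, tangent_sd)
      }
    }
    s + matrix(stats::rnorm(length(s), 0, iso_sd), nrow(s))
  })
  list(configs = configs,
       truth = .ground_truth("gen_configurations3d", seed,
                             list(tangent_sd = tangent_sd, iso_sd = iso_sd,
                                  n = n)))
}

#' Synthetic log-log allometric reference sample
#'
#' `log10(mass) = a + b * log10(length) + e`, `e ~ N(0, sigma_log10)`.
#'
#' @param a Intercept (log10 kg).
#' @param b Slope.
#' @param sigma_log10 Residual SD in log10 units.
#' @param n Sample size.
#' @param length_range Range of lengths, mm.
#' @param seed Integer seed.
#' @return List: `data` (data frame `taxon`, `length_mm`, `mass_kg`) and
#'   `truth`.
#' @export
gen_allometry <- function(a = -1.74, b = 3.0, sigma_log10 = 0.1, n = 50L,
                          length_range = c(5, 40), seed = 1L) {
  set.seed(seed)
  len <- 10^stats::runif(n, log10(length_range[1]), log10(length_range[2]))
  mass <- 10^(a + b * log10(len) + stats::rnorm(n, 0, sigma_log10))
  list(data = data.frame(taxon = sprintf("taxon%03d", seq_len(n)),
                         length_mm = len, mass_kg = mass,
                         stringsAsFactors = FALSE),
       truth = .ground_truth("gen_allometry", seed,
                             list(a = a, b = b, sigma_log10 = sigma_log10,
                                  n = n)))
}

#' Synthetic posterior tree sample with controlled clade frequency
#'
#' Each draw starts from `base_tree`; with probability `flip_prob` two
#' designated tips are swapped (creating an alternative topology whose
#' clade frequency is controlled), and internal node ages are jittered with
#' Gaussian noise while preserving parent-older-than-child ordering.
#'
#' @param base_tree Rooted ultrametric `phylo` with branch lengths.
#' @param swap_tips Character vector of two tip labels to swap on flips;
#'   defaults to the first two tips.
#' @param flip_prob Probability of the swap per draw.
#' @param age_jitter_sd SD of node-age jitter (same units as branch
#'   lengths).
#' @param n Number of trees.
#' @param seed Integer seed.
#' @return List: `trees` (`multiPhylo`) and `truth`.
#' @export
gen_tree_posterior <- function(base_tree, swap_tips = NULL, flip_prob = 0,
                               age_jitter_sd = 0, n = 100L, seed = 1L) {
  stopifnot(inherits(base_tree, "phylo"))
  if (is.null(swap_tips)) swap_tips <- base_tree$tip.label[1:2]
  if (!all(swap_tips %in% base_tree$tip.label) || length(swap_tips) != 2L)
    stop_invalid("swap_tips must name two tips of the base tree")
  set.seed(seed)
  trees <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- base_tree
    if (stats::runif(1) < flip_prob) {
      a <- match(swap_tips[1], tr$tip.label)
      b <- match(swap_tips[2], tr$tip.label)
      tr$tip.label[c(a, b)] <- tr$tip.label[c(b, a)]
    }
    if (age_jitter_sd > 0) tr <- .jitter_node_ages(tr, age_jitter_sd)
    trees[[i]] <- tr
  }
  class(trees) <- "multiPhylo"
  list(trees = trees,
       truth = .ground_truth("gen_tree_posterior", seed,
                             list(swap_tips = swap_tips,
                                  flip_prob = flip_prob,
                                  age_jitter_sd = age_jitter_sd, n = n)))
}

# jitter internal node ages, constrained between oldest child and parent
.jitter_node_ages <- function(tree, sd) {
  nt <- length(tree$tip.label)
  ages <- .node_ages(tree, warn = FALSE)
  # process internal nodes from root downwards (preorder on edges)
  eo <- ape::reorder.phylo(tree, "cladewise")$edge
  parent_of <- integer(nt + tree$Nnode)
  parent_of[eo[, 2L]] <- eo[, 1L]
  order_nodes <- unique(eo[, 1L])            # root first in cladewise order
  children_of <- split(eo[, 2L], eo[, 1L])
  for (nd in order_nodes) {
    lo <- max(ages[children_of[[as.character(nd)]]])
    hi <- if (parent_of[nd] == 0L) Inf else ages[parent_of[nd]]
    prop <- ages[nd] + stats::rnorm(1, 0, sd)
    ages[nd] <- min(max(prop, lo + 1e-9), if (is.finite(hi)) hi - 1e-9
                    else prop)
    if (ages[nd] < lo) ages[nd] <- lo + 1e-9
  }
  tree$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  tree
}
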