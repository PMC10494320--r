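# Posterior tree-sample summarization: burn-in, clade posterior
# frequencies, maximum-clade-credibility (MCC) tree, node-age HPD
# intervals, and trace effective sample sizes.

#' Read a list of newick trees
#'
#' One tree per line (or semicolon-delimited).  All trees must share one
#' leaf-label set.
#'
#' @param path File of newick strings.
#' @return An `ape::multiPhylo` list, source order preserved.
#' @export
read_newick_list <- function(path) {
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop_invalid("no parseable newick trees in ", path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop_invalid("tree ", i, " has a different taxon set")
  }
  trees
}

#' Write a tree (or trees) to newick
#'
#' @param tree A `phylo` or `multiPhylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Discard burn-in from a posterior tree sample
#'
#' Drops the first `ceiling(fraction * n)` trees.
#'
#' @param trees `multiPhylo` (or list of `phylo`).
#' @param fraction Burn-in fraction in \[0, 1) (default 0.25).
#' @return The retained trees.
#' @export
apply_burnin <- function(trees, fraction = 0.25) {
  if (fraction < 0 || fraction >= 1)
    stop_invalid("burn-in fraction must lie in [0, 1)")
  n <- length(trees)
  drop <- ceiling(fraction * n)
  if (drop >= n) stop_invalid("burn-in would discard every tree")
  trees[(drop + 1L):n]
}

# canonical key of a rooted clade: sorted tip labels joined by "|"
.clade_keys <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  desc <- vector("list", nt + nn)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  # edges in postorder so children are resolved before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(eo))) {
    p <- eo[e, 1L]; ch <- eo[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  internal <- (nt + 1L):(nt + nn)
  keys <- vapply(desc[internal], function(x) paste(sort(x), collapse = "|"), "")
  names(keys) <- as.character(internal)
  keys
}

#' Posterior clade frequencies of a rooted tree sample
#'
#' Clades are rooted taxon subsets (not unrooted bipartitions); the
#' frequency of a clade is the fraction of sample trees containing it.  The
#' all-taxa (root) clade always has frequency 1.
#'
#' @param trees `multiPhylo` or list of rooted `phylo` trees.
#' @return Named numeric vector of frequencies in (0, 1], names are
#'   `"|"`-joined sorted tip labels.
#' @export
clade_frequencies <- function(trees) {
  if (length(trees) < 1L) stop_invalid("empty tree sample")
  counts <- new.env(hash = TRUE)
  for (tr in trees) {
    for (k in unique(.clade_keys(tr)))
      assign(k, (counts[[k]] %||% 0L) + 1L, envir = counts)
  }
  keys <- ls(counts)
  out <- vapply(keys, function(k) counts[[k]], 0L) / length(trees)
  out
}

# node ages from branch lengths; ultrametric trees get height - depth,
# others fall back to root-to-node distances with a warning
.node_ages <- function(tree, warn = TRUE) {
  depth <- ape::node.depth.edgelength(tree)
  nt <- length(tree$tip.label)
  h <- max(depth[seq_len(nt)])
  if (max(h - depth[seq_len(nt)]) > 1e-6 * max(h, 1)) {
    if (warn)
      warning("tree is not ultrametric: node ages reported as root-to-node ",
              "distances", call. = FALSE)
    return(depth)
  }
  h - depth
}

#' Maximum-clade-credibility tree of a posterior sample
#'
#' Scores every sampled tree by the sum of log posterior clade frequencies
#' over its internal clades and returns the argmax (ties broken by earliest
#' index); no consensus tree is synthesized.  Each internal node of the
#' winner is annotated with its clade's posterior support and with the
#' median and HPD interval of its age across the sample trees that contain
#' the clade.
#'
#' @param trees `multiPhylo` or list of rooted trees with branch lengths.
#' @param level HPD mass for node ages (default 0.95).
#' @return Object of class `mcc_result`: `index`, `tree`, `log_score`,
#'   `node_summary` (data frame: `node`, `clade`, `support`, `age_median`,
#'   `age_hpd_low`, `age_hpd_high`, `n_matching`), and `clade_freq`.
#' @export
mcc_tree <- function(trees, level = 0.95) {
  if (length(trees) < 1L) stop_invalid("empty tree sample")
  freq <- clade_frequencies(trees)
  keys_list <- lapply(trees, .clade_keys)
  scores <- vapply(keys_list, function(k) sum(log(freq[k])), 0)
  idx <- which.max(scores)          # which.max takes the earliest maximum
  best <- trees[[idx]]
  nt <- length(best$tip.label)
  keys <- keys_list[[idx]]
  # collect this clade's age in every tree containing it
  ages_by_key <- new.env(hash = TRUE)
  for (i in seq_along(trees)) {
    a <- .node_ages(trees[[i]], warn = (i == 1L))
    k <- keys_list[[i]]
    for (j in seq_along(k)) {
      key <- k[j]
      node <- as.integer(names(k)[j])
      assign(key, c(ages_by_key[[key]] %||% numeric(0), a[node]),
             envir = ages_by_key)
    }
  }
  node_summary <- do.call(rbind, lapply(seq_along(keys), function(j) {
    key <- keys[j]
    ages <- ages_by_key[[key]]
    hpd <- node_age_hpd(ages, level, warn = FALSE)
    data.frame(node = as.integer(names(keys)[j]), clade = key,
               support = unname(freq[key]),
               age_median = stats::median(ages),
               age_hpd_low = hpd[1], age_hpd_high = hpd[2],
               n_matching = length(ages), stringsAsFactors = FALSE)
  }))
  structure(list(index = idx, tree = best, log_score = scores[idx],
                 node_summary = node_summary, clade_freq = freq),
            class = "mcc_result")
}

#' @export
print.mcc_result <- function(x, ...) {
  cat(sprintf("MCC tree: sample index %d, log clade-credibility %.4f\n",
              x$index, x$log_score))
  cat(sprintf("%d internal clades, median support %.2f\n",
              nrow(x$node_summary), stats::median(x$node_summary$support)))
  invisible(x)
}

#' Write an MCC tree with support/HPD annotations
#'
#' Emits newick with BEAST-style bracket comments on internal nodes:
#' `[&posterior=..,height_95%_HPD={..,..}]`.
#'
#' @param mcc An [mcc_tree()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_newick <- function(mcc, path) {
  tree <- mcc$tree
  ns <- mcc$node_summary
  lab <- rep("", tree$Nnode)
  nt <- length(tree$tip.label)
  lab[ns$node - nt] <- sprintf(
    "[&posterior=%.4g,height_95%%_HPD={%.6g,%.6g}]",
    ns$support, ns$age_hpd_low, ns$age_hpd_high)
  tree$node.label <- lab
  writeLines(ape::write.tree(tree), path)
  invisible(path)
}

#' Highest-posterior-density interval of a sample
#'
#' Shortest contiguous interval over the sorted sample containing
#' `ceiling(level * n)` points; ties resolved to the smallest lower bound.
#'
#' @param ages Numeric sample (non-empty).
#' @param level Probability mass (default 0.95).
#' @param warn Warn when n < 20 (default `TRUE`).
#' @return `c(low, high)`.
#' @export
node_age_hpd <- function(ages, level = 0.95, warn = TRUE) {
  if (length(ages) == 0L) stop_invalid("empty sample")
  if (warn && length(ages) < 20L)
    warning("fewer than 20 values: HPD interval is unstable", call. = FALSE)
  s <- sort(ages)
  n <- length(s)
  m <- min(n, ceiling(level * n))
  if (m == n) return(c(s[1], s[n]))
  starts <- seq_len(n - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths)            # earliest minimum: smallest lower bound
  c(s[i], s[i + m - 1L])
}

#' Effective sample size of an MCMC trace
#'
#' \eqn{ESS = n / (1 + 2\sum_k \rho_k)} with the autocorrelation sum
#' truncated by the initial positive-sequence rule: pair consecutive
#' autocorrelations \eqn{\Gamma_m = \rho_{2m} + \rho_{2m+1}} and stop at
#' the first non-positive pair.  Clipped to (0, n].  A constant trace has
#' no autocorrelation structure and is reported as ESS = n with a warning.
#'
#' @param trace Numeric vector (n >= 10).
#' @return Effective sample size.
#' @export
ess <- function(trace) {
  n <- length(trace)
  if (n < 10L) stop_invalid("trace must have at least 10 values")
  if (stats::var(trace) == 0) {
    warning("constant trace: ESS defined as n", call. = FALSE)
    return(as.numeric(n))
  }
  rho <- stats::acf(trace, lag.max = n - 1L, plot = FALSE,
                    demean = TRUE)$acf[, 1L, 1L]
  # Geyer initial positive sequence over pairs (rho_0 + rho_1), ...
  s <- 0
  m <- 0L
  repeat {
    i1 <- 2L * m; i2 <- 2L * m + 1L         # lags
    if (i1 > n - 1L) break
    g <- rho[i1 + 1L] + (if (i2 <= n - 1L) rho[i2 + 1L] else 0)
    if (g <= 0) break
    s <- s + g
    m <- m + 1L
  }
  # s sums rho_0..rho_(2m+1); convert to 1 + 2*sum_{k>=1} rho_k
  denom <- 2 * s - 1
  out <- n / max(denom, 1e-12)
  min(max(out, 1e-12), n)
}

#' Read a tab-separated MCMC trace file
#'
#' @param path TSV with a header row; one column per parameter.
#' @return Data frame of numeric traces.
#' @export
read_trace <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Summary statistics and ESS per trace parameter
#'
#' @param traces Data frame (e.g. from [read_trace()]).
#' @return Data frame: `parameter`, `n`, `mean`, `ess`.
#' @export
trace_stats <- function(traces) {
  do.call(rbind, lapply(names(traces), function(p) {
    v <- traces[[p]]
    data.frame(parameter = p, n = length(v), mean = mean(v), ess = ess(v),
               stringsAsFactors = FALSE)
  }))
}
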