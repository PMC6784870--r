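#' Total phylogenetic diversity of a tree
#'
#' Phylogenetic diversity (PD) is the sum of all branch lengths of the
#' tree (the root edge included when present).
#'
#' @param tree An [ape::phylo] object or a path/string parseable by
#'   [ape::read.tree()].
#' @return Numeric branch-length sum.
#' @examples
#' pd_total(ape::read.tree(text = "((A:1,B:2):0.5,C:3);"))  # 6.5
#' @export
pd_total <- function(tree) {
  tree <- as_phylo(tree)
  s <- sum(tree$edge.length)
  if (!is.null(tree$root.edge)) s <- s + tree$root.edge
  s
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    out <- if (file.exists(tree)) ape::read.tree(tree)
           else ape::read.tree(text = tree)
    if (is.null(out)) stop("could not parse Newick input", call. = FALSE)
    return(out)
  }
  stop("tree must be a phylo object or Newick text/path", call. = FALSE)
}

# PD of the subtree induced by a tip set: edges lying on paths between the
# retained tips only. Following the usual Faith's-PD convention, the path
# from the retained subtree's root towards the original root is excluded
# (configurable via include_root_edge). Fewer than 2 tips span no edges.
induced_pd <- function(tree, tips, include_root_edge = FALSE) {
  tips <- intersect(tips, tree$tip.label)
  if (length(tips) < 2L) return(0)
  sub <- ape::keep.tip(tree, tips)
  s <- sum(sub$edge.length)
  if (include_root_edge && !is.null(sub$root.edge)) s <- s + sub$root.edge
  s
}

#' Phylogenetic diversity gained over a baseline tip set
#'
#' Quantifies how much phylogenetic diversity the non-baseline tips
#' (for example, newly recovered uncultured genomes) add to a baseline
#' reference set: `increase% = (PD_all - PD_baseline) / PD_baseline *
#' 100`, where `PD_baseline` is the branch-length sum of the subtree
#' induced by the baseline tips. Optionally computed per group (for
#' example per phylum), restricting both tip sets to each group's tips.
#'
#' @param tree A `phylo` object or Newick text/path.
#' @param baseline_tips Character vector of baseline tip labels.
#' @param groups Optional named vector mapping tip label -> group (for
#'   example phylum); when supplied, a per-group table is returned as
#'   well.
#' @param include_root_edge Count the residual root path of induced
#'   subtrees (default FALSE, the usual Faith's-PD convention).
#' @return List with `pd_all`, `pd_baseline`, `increase_pct` (NA when the
#'   baseline spans no edges) and, when `groups` is given, `by_group`
#'   (data.frame: group, pd_all, pd_baseline, increase_pct; groups with
#'   no baseline tips get NA).
#' @export
pd_increase <- function(tree, baseline_tips, groups = NULL,
                        include_root_edge = FALSE) {
  tree <- as_phylo(tree)
  if (length(intersect(baseline_tips, tree$tip.label)) == 0L)
    stop("baseline_tips shares no labels with the tree", call. = FALSE)
  pd_all <- pd_total(tree)
  pd_base <- induced_pd(tree, baseline_tips, include_root_edge)
  inc <- if (pd_base > 0) (pd_all - pd_base) / pd_base * 100 else NA_real_
  out <- list(pd_all = pd_all, pd_baseline = pd_base, increase_pct = inc)
  if (!is.null(groups)) {
    gs <- sort(unique(groups[tree$tip.label]))
    gs <- gs[!is.na(gs)]
    by_group <- do.call(rbind, lapply(gs, function(g) {
      g_tips <- tree$tip.label[groups[tree$tip.label] %in% g]
      g_base <- intersect(g_tips, baseline_tips)
      g_all_pd <- induced_pd(tree, g_tips, include_root_edge)
      if (length(g_base) == 0L)
        return(data.frame(group = g, pd_all = g_all_pd,
                          pd_baseline = NA_real_,
                          increase_pct = NA_real_))
      g_base_pd <- induced_pd(tree, g_base, include_root_edge)
      data.frame(group = g, pd_all = g_all_pd, pd_baseline = g_base_pd,
                 increase_pct = if (g_base_pd > 0)
                   (g_all_pd - g_base_pd) / g_base_pd * 100 else NA_real_)
    }))
    out$by_group <- by_group
  }
  out
}

#' Bootstrapped species accumulation curve
#'
#' For each sampling depth x = 1..n_samples, draws `n_boot` random
#' subsets of x samples (without replacement within a subset), counts the
#' species detected in at least one sample of the subset, and averages.
#' Deterministic given the seed.
#'
#' @param detections Logical (or 0/1) matrix, samples in rows, species in
#'   columns; `TRUE` = species detected in sample.
#' @param n_boot Bootstrap replicates per sampling depth, default 10.
#' @param seed RNG seed.
#' @return Object of class `accumulation_curve`: list with `x`, `y_mean`,
#'   `y_sd`, `n_boot`.
#' @export
accumulation_curve <- function(detections, n_boot = 10, seed = 1) {
  detections <- as.matrix(detections) > 0
  n <- nrow(detections)
  if (n == 0L || ncol(detections) == 0L)
    stop("detections matrix must be non-empty", call. = FALSE)
  res <- with_seed(seed, {
    vapply(seq_len(n), function(x) {
      rich <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, x)
        sum(colSums(detections[idx, , drop = FALSE]) > 0)
      }, numeric(1))
      c(mean(rich), sd(rich))
    }, numeric(2))
  })
  structure(list(x = seq_len(n), y_mean = res[1, ],
                 y_sd = ifelse(is.na(res[2, ]), 0, res[2, ]),
                 n_boot = n_boot),
            class = "accumulation_curve")
}

#' Asymptotic regression of an accumulation curve
#'
#' Fits the first-order asymptotic model
#' `y = Asym + (R0 - Asym) * exp(-exp(lrc) * x)` by nonlinear least
#' squares ([stats::nls()] with the [stats::SSasymp()] self-start, which
#' initialises Asym near the curve plateau and lrc from the log-linear
#' decay of residuals), falling back to a Levenberg-Marquardt fit
#' ([minpack.lm::nlsLM()]) when the Gauss-Newton iteration fails.
#' Non-convergence never throws: degenerate inputs (for example a flat
#' curve) are returned with `converged = FALSE` and `Asym` set to the
#' curve mean.
#'
#' @param x,y Curve coordinates (at least 4 points), or an
#'   `accumulation_curve` in `x` with `y` missing.
#' @return List with `Asym`, `R0`, `lrc`, `converged`, `degenerate`,
#'   `fitted`, `residual_ss`.
#' @export
fit_asymptotic <- function(x, y = NULL) {
  if (inherits(x, "accumulation_curve") && is.null(y)) {
    y <- x$y_mean; x <- x$x
  }
  if (length(x) < 4L || length(x) != length(y))
    stop("need at least 4 (x, y) points", call. = FALSE)
  dat <- data.frame(x = as.numeric(x), y = as.numeric(y))
  degenerate <- sd(dat$y) == 0
  fit <- NULL
  if (!degenerate) {
    fit <- tryCatch(
      nls(y ~ SSasymp(x, Asym, R0, lrc), data = dat,
          control = nls.control(maxiter = 200, scaleOffset = 1)),
      error = function(e) NULL)
    if (is.null(fit)) {
      start <- list(Asym = max(dat$y), R0 = dat$y[1],
                    lrc = log(1 / max(dat$x)))
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ Asym + (R0 - Asym) * exp(-exp(lrc) * x),
                          data = dat, start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    }
  }
  if (is.null(fit)) {
    return(list(Asym = mean(dat$y), R0 = dat$y[1], lrc = NA_real_,
                converged = FALSE, degenerate = degenerate,
                fitted = rep(mean(dat$y), nrow(dat)),
                residual_ss = sum((dat$y - mean(dat$y))^2)))
  }
  cf <- coef(fit)
  list(Asym = unname(cf["Asym"]), R0 = unname(cf["R0"]),
       lrc = unname(cf["lrc"]), converged = TRUE, degenerate = FALSE,
       fitted = as.numeric(fitted(fit)),
       residual_ss = sum(resid(fit)^2))
}
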