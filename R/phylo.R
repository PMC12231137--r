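# Phylogenetics: neighbor joining from a distance matrix, ILR balances,
# greedy ILR phylofactorization against a covariate, and phylogenetic signal
# (Blomberg's K, Pagel's lambda) with PGLS.
#
# Signal statistics need a shared-path covariance matrix, which requires a
# root convention: unrooted trees are midpoint rooted (phangorn) solely to
# define C.

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step join the pair minimizing
#' `Q(i,j) = (r-2) d_ij - R_i - R_j`, with the standard branch-length
#' formulas. A negative branch length is clamped to 0 and its deficit moved
#' to the sister branch (their sum, `d_ij`, is preserved). The result is an
#' unrooted tree; on an additive matrix the leaf-to-leaf path lengths
#' reproduce the input exactly.
#'
#' @param d Symmetric non-negative distance matrix over `>= 3` taxa, with
#'   dimnames.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs >= 3 taxa")
  labels <- rownames(d)
  # each active cluster carries its Newick fragment
  nwk <- labels
  active <- seq_len(n)
  D <- d
  fmt <- function(x) sprintf("%.12g", x)
  while (length(active) > 3L) {
    r <- length(active)
    Dm <- D[active, active]
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1L, ]
    i <- ij[1L]; j <- ij[2L]
    dij <- Dm[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- dij; li <- 0 }
    if (lj < 0) { li <- dij; lj <- 0 }
    ai <- active[i]; aj <- active[j]
    # distances from the new node u to every other active cluster
    rest <- active[-c(i, j)]
    du <- (D[ai, rest] + D[aj, rest] - dij) / 2
    u <- nrow(D) + 1L
    D <- rbind(cbind(D, 0), 0)
    D[u, rest] <- D[rest, u] <- du
    nwk[u] <- paste0("(", nwk[ai], ":", fmt(li), ",", nwk[aj], ":", fmt(lj), ")")
    active <- c(rest, u)
  }
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- D[a, b] - la
  lc <- D[a, c3] - la
  if (la < 0) { lb <- lb + la; lc <- lc + la; la <- 0 }
  if (lb < 0) { lb <- 0 }
  if (lc < 0) { lc <- 0 }
  txt <- paste0("(", nwk[a], ":", fmt(la), ",", nwk[b], ":", fmt(lb), ",",
                nwk[c3], ":", fmt(lc), ");")
  ape::read.tree(text = txt)
}

#' Isometric log-ratio balance between two taxon groups
#'
#' Per sample `j`: `y_j = sqrt(r s / (r + s)) * ln(gm_R(j) / gm_S(j))`, where
#' the geometric means are over relative abundances after adding `pseudocount`
#' to every count and re-closing, and `r`, `s` are the group sizes.
#'
#' @param counts Count matrix.
#' @param group_R,group_S Disjoint, non-empty character vectors of taxon ids.
#' @param pseudocount Added to all counts before closure (default 1).
#' @return Named numeric vector of per-sample balances.
#' @export
ilr_balance <- function(counts, group_R, group_S, pseudocount = 1) {
  if (length(intersect(group_R, group_S)))
    stop("ILR groups must be disjoint")
  if (!length(group_R) || !length(group_S))
    stop("ILR groups must be non-empty")
  miss <- setdiff(c(group_R, group_S), rownames(counts))
  if (length(miss)) stop("taxa not in count table: ", paste(miss, collapse = ", "))
  x <- counts + pseudocount
  rel <- sweep(x, 2L, colSums(x), "/")
  r <- length(group_R); s <- length(group_S)
  gmR <- exp(colMeans(log(rel[group_R, , drop = FALSE])))
  gmS <- exp(colMeans(log(rel[group_S, , drop = FALSE])))
  sqrt(r * s / (r + s)) * log(gmR / gmS)
}

# Tip-set bipartitions induced by each edge of an (unrooted) tree.
# Returns a list: per edge, the tip labels on the child side.
edge_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  children <- tree$edge[, 2L]
  sets <- vector("list", nrow(tree$edge))
  # postorder accumulation of tip sets below each node
  below <- vector("list", max(tree$edge))
  for (i in seq_len(n)) below[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ord))) {
    par <- ord[k, 1L]; ch <- ord[k, 2L]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  for (k in seq_len(nrow(tree$edge))) sets[[k]] <- below[[children[k]]]
  sets
}

#' Greedy ILR phylofactorization
#'
#' Iteratively selects the tree edge whose induced taxon contrast best
#' explains a covariate, splitting the taxon set into bins. At each step,
#' candidate edges are those whose tip bipartition cuts exactly one current
#' bin non-trivially (so successive contrasts form a sequential binary
#' partition). The objective is:
#' \itemize{
#' \item `mode = "taxon"` (covariate per taxon, e.g. SNB): absolute pooled
#'   two-sample t statistic comparing covariate values between the edge's two
#'   groups within the bin; p from the two-sided t test.
#' \item `mode = "sample"` (covariate per sample, e.g. pH): F statistic of
#'   regressing the groups' [ilr_balance()] on the covariate; p from the F
#'   test.
#' }
#' A factor is flagged significant when `p < alpha`.
#'
#' @param counts Count matrix (used for balances; required in both modes).
#' @param tree Unrooted tree, tips matching `rownames(counts)`.
#' @param covariate Named numeric vector: per taxon (`mode = "taxon"`) or per
#'   sample (`mode = "sample"`), complete for its mode.
#' @param mode `"taxon"` or `"sample"`.
#' @param n_factors Number of factors to extract (default 15; truncated with
#'   a warning if the tree has fewer usable edges).
#' @param alpha Significance threshold (default 0.01).
#' @param pseudocount Passed to [ilr_balance()].
#' @return Object of class `phylofactor_result`: `factors` (data.frame with
#'   factor index, edge, group sizes, objective, p_value, significant) and
#'   `groups` (per factor, the two taxon id vectors), plus `bins`, the final
#'   binning.
#' @export
phylofactor <- function(counts, tree, covariate, mode = c("taxon", "sample"),
                        n_factors = 15, alpha = 0.01, pseudocount = 1) {
  mode <- match.arg(mode)
  taxa <- tree$tip.label
  if (!all(taxa %in% rownames(counts)))
    stop("tree tips missing from count table")
  if (mode == "taxon") {
    if (!all(taxa %in% names(covariate)))
      stop("per-taxon covariate incomplete")
    cov_t <- covariate[taxa]
    if (any(is.na(cov_t))) stop("per-taxon covariate has missing values")
  } else {
    if (!all(colnames(counts) %in% names(covariate)))
      stop("per-sample covariate incomplete")
    cov_s <- covariate[colnames(counts)]
    if (any(is.na(cov_s))) stop("per-sample covariate has missing values")
  }
  sets <- edge_tip_sets(tree)
  # drop duplicate bipartitions (the two root-adjacent edges of the stored
  # rooted representation can induce complementary = identical splits)
  keys <- vapply(sets, function(s) {
    s <- sort(s)
    comp <- sort(setdiff(taxa, s))
    paste(if (length(s) <= length(comp)) s else comp, collapse = "|")
  }, character(1L))
  keep <- !duplicated(keys) & lengths(sets) < length(taxa)
  sets <- sets[keep]
  edge_ids <- which(keep)

  bins <- list(taxa)
  factors <- list(); groups <- list()
  n_req <- n_factors
  for (f in seq_len(n_req)) {
    best <- NULL
    for (k in seq_along(sets)) {
      s <- sets[[k]]
      cut_bin <- 0L
      for (b in seq_along(bins)) {
        ns <- sum(bins[[b]] %in% s)
        if (ns > 0L && ns < length(bins[[b]])) {
          if (cut_bin > 0L) { cut_bin <- -1L; break }
          cut_bin <- b
        }
      }
      if (cut_bin <= 0L) next
      bin <- bins[[cut_bin]]
      gR <- intersect(bin, s); gS <- setdiff(bin, s)
      obj <- objective_for_split(gR, gS, mode,
                                 if (mode == "taxon") cov_t else cov_s,
                                 counts, pseudocount)
      if (is.null(best) || (!is.na(obj$stat) && (is.na(best$stat) ||
                                                 obj$stat > best$stat))) {
        best <- c(obj, list(bin_idx = cut_bin, gR = gR, gS = gS,
                            edge = edge_ids[k]))
      }
    }
    if (is.null(best)) {
      warning("phylofactor: only ", f - 1L, " of ", n_req,
              " factors available; truncated")
      break
    }
    factors[[f]] <- data.frame(
      factor = f, edge = best$edge,
      n_group_R = length(best$gR), n_group_S = length(best$gS),
      objective = if (is.na(best$stat)) 0 else best$stat,
      p_value = best$p,
      significant = !is.na(best$p) && best$p < alpha)
    groups[[f]] <- list(group_R = best$gR, group_S = best$gS)
    bins <- c(bins[-best$bin_idx], list(best$gR), list(best$gS))
  }
  structure(list(factors = do.call(rbind, factors), groups = groups,
                 bins = bins, mode = mode, alpha = alpha),
            class = "phylofactor_result")
}

objective_for_split <- function(gR, gS, mode, covariate, counts, pseudocount) {
  if (mode == "taxon") {
    x <- covariate[gR]; y <- covariate[gS]
    nx <- length(x); ny <- length(y)
    if (nx + ny < 3L) return(list(stat = NA_real_, p = NA_real_))
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
    if (sp2 <= 0) return(list(stat = NA_real_, p = NA_real_))
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    p <- 2 * stats::pt(abs(tt), df = nx + ny - 2, lower.tail = FALSE)
    list(stat = abs(tt), p = p)
  } else {
    y <- ilr_balance(counts, gR, gS, pseudocount)
    if (stats::sd(covariate) == 0 || stats::sd(y) == 0)
      return(list(stat = NA_real_, p = NA_real_))
    fit <- stats::lm(y ~ covariate)
    a <- stats::anova(fit)
    list(stat = a[["F value"]][1L], p = a[["Pr(>F)"]][1L])
  }
}

#' @export
print.phylofactor_result <- function(x, ...) {
  cat("Phylofactorization (", x$mode, " mode): ",
      nrow(x$factors), " factors, ", sum(x$factors$significant),
      " significant at alpha = ", x$alpha, "\n", sep = "")
  print(x$factors, row.names = FALSE)
  invisible(x)
}

# Shared-path covariance of a tree (midpoint rooted if needed), tips ordered
# as tip.label.
phylo_vcv <- function(tree) {
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  ape::vcv(tree)
}

#' Blomberg's K with permutation test
#'
#' `K = (MSE0/MSE) / E[MSE0/MSE]`, where `MSE0` is the variance of tip values
#' about the phylogenetically weighted mean, `MSE` the generalized
#' (C-weighted) residual variance, and the expectation is taken under
#' Brownian motion on the tree: `(tr(C) - n / sum(C^-1)) / (n - 1)`. `K = 1`
#' is the Brownian expectation; `K < 1` means less signal than Brownian.
#' The p-value is the proportion of tip-label permutations (the observed
#' labelling included) whose `MSE0/MSE` is at least the observed one.
#'
#' @param tree Tree (rooted or unrooted; unrooted trees are midpoint rooted
#'   to define the covariance).
#' @param tip_values Named numeric vector over tips; non-constant, complete.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return List of class `phylo_signal_k`: `K`, `p_value`, `n_tips`.
#' @export
blomberg_k <- function(tree, tip_values, n_perm = 999, seed = NULL) {
  y <- tip_values[tree$tip.label]
  if (any(is.na(y))) stop("tip_values incomplete")
  if (stats::sd(y) == 0) stop("tip_values constant")
  n <- length(y)
  C <- phylo_vcv(tree)
  Cinv <- solve(C)
  one <- rep(1, n)
  w <- as.vector(Cinv %*% one) / sum(Cinv)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  ratio <- function(yy) {
    a <- sum(w * yy)
    r <- yy - a
    mse0 <- sum(r^2) / (n - 1)
    mse <- as.numeric(crossprod(r, Cinv %*% r)) / (n - 1)
    mse0 / mse
  }
  obs <- ratio(y)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) ratio(sample(y)), numeric(1L))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  structure(list(K = obs / expected, p_value = p, n_tips = n),
            class = "phylo_signal_k")
}

#' @export
print.phylo_signal_k <- function(x, ...) {
  cat("Blomberg's K =", format(x$K, digits = 4),
      " (permutation p =", format(x$p_value, digits = 3),
      ",", x$n_tips, "tips)\n")
  invisible(x)
}

lambda_scale <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Profile log-likelihood of lambda for an intercept-only Brownian model:
# mu and sigma^2 are profiled analytically.
lambda_loglik <- function(lambda, C, y) {
  n <- length(y)
  Cl <- lambda_scale(C, lambda)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  Cinv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Cinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Cinv_y) / sum(Cinv_1)
  r <- y - mu
  Cinv_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- as.numeric(crossprod(r, Cinv_r)) / n
  -n / 2 * log(2 * pi * s2) - logdet / 2 - n / 2
}

#' Pagel's lambda by maximum likelihood
#'
#' Scales the off-diagonal of the phylogenetic covariance by `lambda` and
#' maximizes the profile likelihood (mean and variance profiled analytically)
#' over `lambda` in `[0, 1]` by bounded scalar optimization (tolerance 1e-6),
#' with the endpoints checked explicitly. `lambda = 0` is no signal,
#' `lambda = 1` full Brownian covariance.
#'
#' @param tree Tree (midpoint rooted internally if unrooted).
#' @param tip_values Named numeric vector over tips.
#' @return List of class `phylo_signal_lambda`: `lambda`, `loglik`, `n_tips`.
#' @export
pagel_lambda <- function(tree, tip_values) {
  y <- tip_values[tree$tip.label]
  if (any(is.na(y))) stop("tip_values incomplete")
  if (stats::sd(y) == 0) stop("tip_values constant")
  C <- phylo_vcv(tree)
  opt <- stats::optimize(lambda_loglik, c(0, 1), C = C, y = y,
                         maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, lambda_loglik(0, C, y)),
                c(1, lambda_loglik(1, C, y)))
  best <- cand[which.max(cand[, 2L]), ]
  structure(list(lambda = best[1L], loglik = best[2L], n_tips = length(y)),
            class = "phylo_signal_lambda")
}

#' @export
print.phylo_signal_lambda <- function(x, ...) {
  cat("Pagel's lambda =", format(x$lambda, digits = 4),
      " (log-likelihood", format(x$loglik, digits = 6),
      ",", x$n_tips, "tips)\n")
  invisible(x)
}

#' Phylogenetic generalized least squares
#'
#' GLS regression with covariance `C(lambda)`:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`, Wald t-tests on `n - p` degrees of
#' freedom. `lambda` is estimated by profile ML over the regression model
#' when not supplied.
#'
#' @param tree Tree over the observations' taxa.
#' @param y Named numeric response per taxon.
#' @param X Predictor matrix (or vector) with rows named by taxon; an
#'   intercept column is added.
#' @param lambda Fixed lambda in `[0, 1]`, or `NULL` to estimate.
#' @return List of class `pgls_fit`: `coefficients` table (estimate, se, t,
#'   p), `lambda`, `sigma2`, `df_residual`, `loglik`.
#' @export
pgls <- function(tree, y, X, lambda = NULL) {
  tips <- tree$tip.label
  y <- y[tips]
  if (is.null(dim(X))) X <- matrix(X[tips], dimnames = list(tips, "x"))
  else X <- X[tips, , drop = FALSE]
  if (any(is.na(y)) || any(is.na(X))) stop("pgls requires complete cases")
  Xd <- cbind(`(Intercept)` = 1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop("rank-deficient predictor matrix")
  C <- phylo_vcv(tree)
  n <- length(y); p <- ncol(Xd)
  fit_at <- function(lam) {
    Cl <- lambda_scale(C, lam)
    ch <- chol(Cl)
    wy <- forwardsolve(t(ch), y)
    wX <- forwardsolve(t(ch), Xd)
    qrX <- qr(wX)
    beta <- qr.coef(qrX, wy)
    r <- wy - wX %*% beta
    rss <- sum(r^2)
    logdet <- 2 * sum(log(diag(ch)))
    ll <- -n / 2 * log(2 * pi * rss / n) - logdet / 2 - n / 2
    list(beta = beta, rss = rss, ll = ll, wX = wX)
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(function(l) fit_at(l)$ll, c(0, 1), maximum = TRUE,
                           tol = 1e-6)
    cand <- c(opt$maximum, 0, 1)
    lls <- vapply(cand, function(l) fit_at(l)$ll, numeric(1L))
    lambda <- cand[which.max(lls)]
  }
  f <- fit_at(lambda)
  sigma2 <- f$rss / (n - p)
  XtX_inv <- chol2inv(qr.R(qr(f$wX)))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- as.vector(f$beta) / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  coefs <- data.frame(estimate = as.vector(f$beta), se = se, t = tval,
                      p_value = pval, row.names = colnames(Xd))
  structure(list(coefficients = coefs, lambda = lambda, sigma2 = sigma2,
                 df_residual = n - p, loglik = f$ll),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (lambda =", format(x$lambda, digits = 4), "):\n")
  print(x$coefficients)
  invisible(x)
}
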