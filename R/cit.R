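#' Permutation-framework association test between a covariate and pattern labels
#'
#' The conditional-inference independence test used at every node of the
#' tree: the linear statistic \eqn{T = \sum_i w_i g(x_i) h(y_i)^\top}
#' (identity transformation for ordered covariates, indicator coding for
#' categorical ones; multinomial class indicators as the outcome influence
#' function) is standardized by its conditional expectation and covariance
#' under the permutation distribution, and the quadratic form
#' \eqn{c = (vec(T) - \mu)^\top \Sigma^{+} (vec(T) - \mu)} (Moore-Penrose
#' inverse, handling the rank deficiency of the class indicators) is
#' referred to its asymptotic chi-squared distribution with
#' \eqn{df = rank(\Sigma)}. Optionally a Monte-Carlo permutation p-value is
#' computed by permuting `y`.
#'
#' @param x covariate (numeric, or factor for categorical).
#' @param y outcome labels (factor; at least 2 classes present).
#' @param weights nonnegative case weights (default 1).
#' @param B number of Monte-Carlo permutations (0 = asymptotic only).
#' @param seed seed for the permutations.
#' @return list: `statistic`, `df`, `p_value` (asymptotic), `p_mc`
#'   (`NA` unless `B > 0`).
#' @export
cit_association_test <- function(x, y, weights = NULL, B = 0L, seed = 1L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 outcome classes in the node")
  g <- if (is.factor(x)) {
    x <- droplevels(x)
    if (nlevels(x) < 2L) stop("constant covariate in node")
    stats::model.matrix(~ x - 1)
  } else {
    if (length(unique(x)) < 2L) stop("constant covariate in node")
    matrix(as.numeric(x), ncol = 1)
  }
  h <- stats::model.matrix(~ y - 1)
  n <- length(y)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  W <- sum(w)
  gw <- g * w
  Sg <- colSums(gw)
  Gw <- crossprod(gw, g)
  Eh <- colSums(h * w) / W
  hc <- sweep(h, 2, Eh)
  Vh <- crossprod(hc * w, hc) / W
  Tm <- crossprod(gw, h)
  mu <- outer(Sg, Eh)
  Sigma <- W / (W - 1) * kronecker(Vh, Gw) -
    1 / (W - 1) * kronecker(Vh, outer(Sg, Sg))
  d <- as.vector(Tm - mu)
  eg <- eigen(Sigma, symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  pos <- eg$values > tol
  df <- sum(pos)
  proj <- crossprod(eg$vectors[, pos, drop = FALSE], d)
  stat <- sum(proj^2 / eg$values[pos])
  # log-scale p-value: extreme associations underflow double precision,
  # and split selection must still discriminate among them
  log_p <- stats::pchisq(stat, df, lower.tail = FALSE, log.p = TRUE)
  p <- exp(log_p)
  p_mc <- NA_real_
  if (B > 0) {
    set.seed(as.integer(seed))
    U <- eg$vectors[, pos, drop = FALSE]
    lam <- eg$values[pos]
    stats_mc <- replicate(B, {
      Tb <- crossprod(gw, h[sample.int(n), , drop = FALSE])
      db <- as.vector(Tb - mu)
      pj <- crossprod(U, db)
      sum(pj^2 / lam)
    })
    p_mc <- (1 + sum(stats_mc >= stat)) / (B + 1)
  }
  list(statistic = stat, df = df, p_value = p, log_p = log_p, p_mc = p_mc)
}

# Moore-Penrose inverse via symmetric eigendecomposition
sym_pinv <- function(M) {
  eg <- eigen(M, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-10
  if (!any(pos)) return(matrix(0, nrow(M), ncol(M)))
  eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
}

# best binary split of a node: maximizes the standardized two-sample
# statistic c_a = (T_a - a E(h))' Vh^+ (T_a - a E(h)) / [a (n-a) / (n-1)]
best_split <- function(x, h, min_bucket) {
  n <- nrow(h)
  Eh <- colMeans(h)
  Vh <- crossprod(sweep(h, 2, Eh)) / n
  A <- sym_pinv(Vh)
  if (is.factor(x)) {
    lev <- levels(droplevels(x))
    L <- length(lev)
    if (L < 2L) return(NULL)
    subsets <- lapply(seq_len(2^(L - 1) - 1), function(m) {
      lev[bitwAnd(m, 2^(seq_len(L) - 1)) > 0]
    })
    best <- NULL
    for (s in subsets) {
      left <- x %in% s
      a <- sum(left)
      if (a < min_bucket || n - a < min_bucket) next
      Ta <- colSums(h[left, , drop = FALSE])
      d <- Ta - a * Eh
      cs <- drop(t(d) %*% A %*% d) / (a * (n - a) / (n - 1))
      if (is.null(best) || cs > best$stat) {
        best <- list(type = "categorical", levels_left = s, stat = cs)
      }
    }
    best
  } else {
    ord <- order(x)
    xs <- x[ord]
    Hc <- apply(h[ord, , drop = FALSE], 2, cumsum)
    a_all <- seq_len(n - 1)
    ok <- a_all >= min_bucket & (n - a_all) >= min_bucket &
      xs[a_all] < xs[a_all + 1]
    if (!any(ok)) return(NULL)
    a <- a_all[ok]
    D <- Hc[a, , drop = FALSE] - outer(a, Eh)
    cs <- rowSums((D %*% A) * D) / (a * (n - a) / (n - 1))
    i <- which.max(cs)
    list(type = "numeric", cut = unname(xs[a[i]]), stat = unname(cs[i]))
  }
}

#' Grow a conditional inference tree over the predicted optimal patterns
#'
#' Recursive partitioning with permutation-test split selection: at each
#' node every (non-constant) predictor is tested against the outcome with
#' [cit_association_test()], p-values are Bonferroni-adjusted across the
#' predictors tested, and the node becomes a leaf if the smallest adjusted
#' p-value exceeds `alpha` or the size/depth limits bind. Otherwise the
#' most significant predictor is split at the cutpoint maximizing the
#' standardized two-sample statistic (ties in adjusted p broken by the
#' order of `predictors`), and growing recurses into the children.
#'
#' @param data data.frame holding outcome and predictors.
#' @param outcome name of the outcome column (factor; typically the
#'   predicted optimal pattern).
#' @param predictors character vector of predictor columns.
#' @param alpha significance threshold for the adjusted p-value.
#' @param min_node minimum node size eligible for splitting.
#' @param min_bucket minimum child size.
#' @param max_depth maximum depth (0 = root only).
#' @return object of class `cit_tree`: `root` (nested node list), `alpha`,
#'   `predictors`, `outcome`, `levels`, `n`.
#' @export
grow_cit <- function(data, outcome = "optimal", predictors,
                     alpha = 0.05, min_node = 200L, min_bucket = 20L,
                     max_depth = 5L) {
  y <- as.factor(data[[outcome]])
  if (any(is.na(y))) stop("missing outcome values")
  for (v in predictors) if (any(is.na(data[[v]]))) {
    stop("missing predictor values in '", v, "' (complete cases only)")
  }
  counter <- new.env()
  counter$id <- 0L

  build <- function(idx, depth) {
    counter$id <- counter$id + 1L
    node <- list(id = counter$id, n = length(idx), depth = depth,
                 dist = prop.table(table(y[idx])), split = NULL,
                 p_adj = NULL, children = NULL)
    yi <- droplevels(y[idx])
    if (length(idx) < min_node || depth >= max_depth || nlevels(yi) < 2L) {
      return(node)
    }
    log_p <- rep(NA_real_, length(predictors))
    names(log_p) <- predictors
    for (v in predictors) {
      xv <- data[[v]][idx]
      testable <- if (is.factor(xv)) nlevels(droplevels(xv)) > 1L
                  else length(unique(xv)) > 1L
      if (testable) log_p[v] <- cit_association_test(xv, yi)$log_p
    }
    tested <- !is.na(log_p)
    if (!any(tested)) return(node)
    # Bonferroni on the log scale: selection among extreme associations
    # stays well-defined even where exp(log_p) underflows to zero
    log_p_adj <- pmin(log_p + log(sum(tested)), 0)  # names kept from 1st arg
    node$p_adj <- exp(log_p_adj)
    if (min(log_p_adj, na.rm = TRUE) > log(alpha)) return(node)
    v_best <- predictors[tested][which.min(log_p_adj[tested])]
    h <- stats::model.matrix(~ yi - 1)
    sp <- best_split(data[[v_best]][idx], h, min_bucket)
    if (is.null(sp)) return(node)
    left <- if (sp$type == "numeric") data[[v_best]][idx] <= sp$cut
            else data[[v_best]][idx] %in% sp$levels_left
    node$split <- c(list(var = v_best,
                         p_adj = unname(exp(log_p_adj[v_best]))), sp)
    node$children <- list(build(idx[left], depth + 1L),
                          build(idx[!left], depth + 1L))
    node
  }
  structure(list(root = build(seq_len(nrow(data)), 0L), alpha = alpha,
                 predictors = predictors, outcome = outcome,
                 levels = levels(y), n = nrow(data)),
            class = "cit_tree")
}

#' @export
print.cit_tree <- function(x, ...) {
  cat("conditional inference tree: n =", x$n, ", alpha =", x$alpha, "\n")
  rec <- function(node, indent, label) {
    cat(strrep("  ", indent), "[", node$id, "] ", label, " n=", node$n, sep = "")
    if (is.null(node$split)) {
      cat("  leaf:", paste(sprintf("%s %.2f", names(node$dist), node$dist),
                           collapse = ", "), "\n")
    } else {
      s <- node$split
      desc <- if (s$type == "numeric") paste0(s$var, " <= ", signif(s$cut, 4))
              else paste0(s$var, " in {", paste(s$levels_left, collapse = ","), "}")
      cat("  split ", desc, sprintf(" (p_adj = %.3g)\n", s$p_adj), sep = "")
      rec(node$children[[1]], indent + 1, "yes:")
      rec(node$children[[2]], indent + 1, "no: ")
    }
  }
  rec(x$root, 0, "root")
  invisible(x)
}

#' Depth of a conditional inference tree
#'
#' @param tree a `cit_tree`.
#' @return integer; 0 for a root-only tree.
#' @export
cit_depth <- function(tree) {
  rec <- function(node) {
    if (is.null(node$split)) return(node$depth)
    max(rec(node$children[[1]]), rec(node$children[[2]]))
  }
  rec(tree$root)
}

#' Route observations through a conditional inference tree
#'
#' @param tree a `cit_tree`.
#' @param newdata data.frame containing the split covariates.
#' @return list: `leaf` (leaf node id per row), `majority` (factor of
#'   majority class per row), `dist` (matrix of leaf class distributions,
#'   one row per observation).
#' @export
cit_predict <- function(tree, newdata) {
  n <- nrow(newdata)
  leaf <- integer(n)
  dist <- matrix(0, n, length(tree$levels),
                 dimnames = list(NULL, tree$levels))
  route <- function(node, idx) {
    if (!length(idx)) return()
    if (is.null(node$split)) {
      leaf[idx] <<- node$id
      d <- rep(0, length(tree$levels)); names(d) <- tree$levels
      d[names(node$dist)] <- node$dist
      dist[idx, ] <<- matrix(d, length(idx), length(d), byrow = TRUE)
      return()
    }
    s <- node$split
    if (!s$var %in% names(newdata)) stop("missing split covariate: ", s$var)
    xv <- newdata[[s$var]][idx]
    left <- if (s$type == "numeric") xv <= s$cut else xv %in% s$levels_left
    route(node$children[[1]], idx[left])
    route(node$children[[2]], idx[!left])
  }
  route(tree$root, seq_len(n))
  list(leaf = leaf,
       majority = factor(tree$levels[max.col(dist, ties.method = "first")],
                         levels = tree$levels),
       dist = dist)
}
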