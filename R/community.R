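as_abundance_matrix <- function(x, axis = c("samples", "otus")) {
  axis <- match.arg(axis)
  m <- if (inherits(x, "trf_otu_table")) x$abundance else as.matrix(x)
  if (axis == "otus") m <- t(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(a, b) = 1 - 2 sum(min(a_i, b_i)) / (sum a_i + sum b_i), computed between
#' samples (rows) or between OTU abundance profiles (columns).
#'
#' @param x a `"trf_otu_table"` or a non-negative samples x OTUs matrix.
#' @param axis `"samples"` (default) or `"otus"`.
#' @return A symmetric matrix of class `"bray_dist"` with zero diagonal and
#'   entries in [0, 1].
#' @export
bray_curtis <- function(x, axis = c("samples", "otus")) {
  m <- as_abundance_matrix(x, axis)
  if (any(m < 0)) stop_input("abundances must be non-negative")
  zero <- rowSums(m) == 0
  if (any(zero))
    stop_input("zero-sum row(s): ", paste(rownames(m)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  structure(d, class = c("bray_dist", "matrix"))
}

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(as.matrix(d))
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
    stop_input("a symmetric distance matrix is required")
  d
}

#' UPGMA hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative average-linkage (UPGMA) clustering via [stats::hclust()].
#'
#' @param d distance matrix (class `"bray_dist"`, `"dist"` or plain matrix).
#' @return An `"hclust"` tree.
#' @export
hierarchical_cluster <- function(d) {
  d <- as_dist_matrix(d)
  if (nrow(d) < 2) stop_input("at least two objects are required")
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Nonmetric multidimensional scaling with restarts
#'
#' Kruskal stress-1 NMDS via [vegan::monoMDS()] (global model), taking the
#' best of `n_restarts` starts: the first start is the metric (principal
#' coordinates) configuration, the remaining ones are seeded random Gaussian
#' configurations. Scores are centred. Fully reproducible under a fixed seed.
#'
#' @param d distance matrix.
#' @param k number of ordination dimensions (default 2).
#' @param n_restarts number of starts (default 20).
#' @param seed integer seed (required for reproducibility).
#' @param maxit,tol iteration cap and stress convergence tolerance.
#' @return Object of class `"nmds_fit"`: `points` (n x k), `stress`
#'   (Kruskal stress-1, as a fraction), `stress_restarts`, `converged` flag
#'   (FALSE in no restart converged), `seed`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = 1, maxit = 300,
                 tol = 1e-7) {
  dm <- as_dist_matrix(d)
  if (k < 1) stop_input("k must be >= 1")
  n <- nrow(dm)
  dd <- stats::as.dist(dm)
  best <- NULL
  stresses <- numeric(n_restarts)
  any_converged <- FALSE
  with_substream(seed, "nmds", {
    for (i in seq_len(n_restarts)) {
      init <- if (i == 1) {
        y <- suppressWarnings(stats::cmdscale(dd, k = k))
        if (ncol(y) < k) cbind(y, matrix(0, n, k - ncol(y))) else y
      } else matrix(stats::rnorm(n * k), n, k)
      fit <- vegan::monoMDS(dd, y = init, k = k, model = "global",
                            maxit = maxit, sratmax = 1 - tol)
      stresses[i] <- fit$stress
      conv <- isTRUE(fit$icause %in% c(3, 4)) || fit$stress < 1e-6
      any_converged <- any_converged || conv
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
  })
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  dimnames(pts) <- list(rownames(dm), paste0("NMDS", seq_len(k)))
  structure(list(points = pts[, , drop = FALSE], stress = best$stress,
                 stress_restarts = stresses, k = k, seed = seed,
                 converged = any_converged),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4g, best of %d restarts%s\n",
              x$k, x$stress, length(x$stress_restarts),
              if (!x$converged) " [no restart converged]" else ""))
  invisible(x)
}

# all permutations of 1..n (n small), in lexicographic order
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (j in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(first, rest[sub[j, ]])
    }
  }
  out
}

#' PERMANOVA: permutational multivariate ANOVA on a distance matrix
#'
#' Partitions the total sum of squared distances (Gower-centred inner
#' product matrix) into sequential (Type I) terms in formula order, computes
#' a pseudo-F per term, and obtains p-values by free permutation of the rows
#' of the distance matrix. When the full permutation count n! does not
#' exceed `exhaustive_cap`, all permutations are enumerated and the p-value
#' is the exact tail proportion (the identity permutation included);
#' otherwise `n_perm` random permutations are drawn and the +1-corrected
#' Monte-Carlo estimate is reported.
#'
#' @param d distance matrix.
#' @param formula right-hand-side formula of factors, e.g.
#'   `~ station + time_point`.
#' @param data data.frame of sample metadata, rows aligned with `d`.
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param exhaustive_cap enumerate all n! permutations when n! <= this cap
#'   (default 10000).
#' @return Object of class `"permanova_fit"` with the ANOVA-style table
#'   (`df`, `SS`, `R2`, `F`, `p`), the permutation count, `exhaustive` flag
#'   and seed. Term R2 plus residual R2 sums to 1.
#' @export
permanova <- function(d, formula, data, n_perm = 999, seed = 1,
                      exhaustive_cap = 10000) {
  dm <- as_dist_matrix(d)
  n <- nrow(dm)
  if (nrow(data) != n) stop_input("metadata rows must match the distance matrix")
  terms_obj <- stats::terms(formula)
  term_labels <- attr(terms_obj, "term.labels")
  if (length(term_labels) == 0) stop_input("formula has no terms")
  for (v in all.vars(formula)) {
    if (!v %in% names(data)) stop_input("factor '", v, "' not found in data")
    if (length(unique(data[[v]])) < 2)
      stop_input("factor '", v, "' is constant")
  }
  grp_sizes <- table(interaction(data[all.vars(formula)], drop = TRUE))
  singleton_groups <- any(grp_sizes == 1)
  if (n_perm < 99) stop_input("n_perm must be >= 99")

  A <- -0.5 * dm^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  ss_total <- sum(diag(G))

  # orthonormal bases of the cumulative model spaces (beyond the intercept)
  qs <- vector("list", length(term_labels))
  dfs <- numeric(length(term_labels))
  prev_rank <- 1
  for (j in seq_along(term_labels)) {
    f <- stats::reformulate(term_labels[seq_len(j)])
    X <- stats::model.matrix(f, data)
    qr_ <- qr(X)
    Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
    qs[[j]] <- Q
    dfs[j] <- qr_$rank - prev_rank
    prev_rank <- qr_$rank
  }
  df_res <- n - prev_rank

  ss_terms_for <- function(Gp) {
    cum <- vapply(qs, function(Q) sum(Q * (Gp %*% Q)), numeric(1))
    ss <- diff(c(0, cum))
    c(ss, ss_total - cum[length(cum)])
  }
  # a residual SS at rounding-error scale is an exact within-group fit
  f_stats <- function(ss) {
    res <- ss[length(ss)]
    if (res < 1e-10 * max(abs(ss_total), 1e-300)) res <- 0
    num <- ss[-length(ss)] / dfs
    den <- res / df_res
    if (den == 0) ifelse(num > 0, Inf, NaN) else num / den
  }

  ss_obs <- ss_terms_for(G)
  F_obs <- f_stats(ss_obs)

  n_fact <- factorial(n)
  exhaustive <- n_fact <= exhaustive_cap
  tol <- 1e-12 * max(1, abs(ss_total))
  at_least <- function(Fp) {
    hit <- Fp >= F_obs - tol |
      (is.infinite(F_obs) & is.infinite(Fp) & Fp > 0)
    hit[is.na(hit)] <- FALSE
    hit
  }
  count <- numeric(length(F_obs))
  if (exhaustive) {
    perms <- all_permutations(n)
    for (r in seq_len(nrow(perms))) {
      p <- perms[r, ]
      count <- count + at_least(f_stats(ss_terms_for(G[p, p])))
    }
    pvals <- count / nrow(perms)
    n_used <- nrow(perms)
  } else {
    with_substream(seed, "permanova", {
      for (r in seq_len(n_perm)) {
        p <- sample.int(n)
        count <- count + at_least(f_stats(ss_terms_for(G[p, p])))
      }
    })
    pvals <- (count + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  pvals[!is.finite(F_obs) & !is.infinite(F_obs)] <- NA_real_
  tab <- data.frame(
    term = c(term_labels, "Residual"),
    df = c(dfs, df_res),
    SS = ss_obs,
    R2 = ss_obs / ss_total,
    F = c(F_obs, NA_real_),
    p = c(pvals, NA_real_),
    stringsAsFactors = FALSE)
  structure(list(table = tab, n = n, n_perm = n_used,
                 exhaustive = exhaustive, seed = seed,
                 singleton_groups = singleton_groups,
                 ss_total = ss_total),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s, %d permutations%s)\n",
              if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$n_perm,
              if (x$singleton_groups) "; singleton group(s) present" else ""))
  print.data.frame(format_sig(x$table, 4), row.names = FALSE)
  invisible(x)
}

#' Fit environmental vectors onto an ordination
#'
#' For each numeric variable, regresses the (centred) variable on the
#' ordination score columns by least squares; reports the squared multiple
#' correlation R2, the unit direction vector of the coefficients on the
#' ordination axes, and a permutation p-value obtained by permuting the
#' variable across samples.
#'
#' @param ord an `"nmds_fit"` or an n x k score matrix.
#' @param env data.frame of per-sample variables (rows aligned with the
#'   ordination).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return Object of class `"env_vectorfit"`: data.frame with one row per
#'   variable (direction cosines, `r2`, `p`, `skipped` for zero-variance
#'   variables).
#' @export
fit_env_vectors <- function(ord, env, n_perm = 999, seed = 1) {
  scores <- if (inherits(ord, "nmds_fit")) ord$points else as.matrix(ord)
  n <- nrow(scores); k <- ncol(scores)
  if (nrow(env) != n) stop_input("env rows must match the ordination")
  Xc <- scale(scores, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Xc))[, seq_len(qr(Xc)$rank), drop = FALSE]
  r2_of <- function(v) {
    vc <- v - mean(v)
    sum((crossprod(Q, vc))^2) / sum(vc^2)
  }
  rows <- vector("list", ncol(env))
  with_substream(seed, "envfit", {
    for (j in seq_len(ncol(env))) {
      v <- env[[j]]
      if (!is.numeric(v)) next
      if (stats::var(v) == 0 || anyNA(v)) {
        rows[[j]] <- data.frame(variable = names(env)[j],
                                t(stats::setNames(rep(NA_real_, k),
                                                  colnames(scores))),
                                r2 = NA_real_, p = NA_real_, skipped = TRUE)
        next
      }
      beta <- stats::coef(stats::lm(v ~ Xc))[-1]
      dir <- beta / sqrt(sum(beta^2))
      r2 <- r2_of(v)
      cnt <- 0
      for (r in seq_len(n_perm)) cnt <- cnt + (r2_of(sample(v)) >= r2 - 1e-12)
      rows[[j]] <- data.frame(variable = names(env)[j],
                              t(stats::setNames(dir, colnames(scores))),
                              r2 = r2, p = (cnt + 1) / (n_perm + 1),
                              skipped = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(vectors = out, n_perm = n_perm, seed = seed),
            class = "env_vectorfit")
}

#' @export
print.env_vectorfit <- function(x, ...) {
  cat("Environmental vector fit (", x$n_perm, " permutations):\n", sep = "")
  print.data.frame(format_sig(x$vectors, 4), row.names = FALSE)
  invisible(x)
}

#' OTU sharing counts between sample groups
#'
#' Counts, for every non-empty combination of groups (Venn cells), the OTUs
#' present in exactly that combination.
#'
#' @param groups named list: each element either a character vector of OTU
#'   ids, or an abundance matrix / `"trf_otu_table"` from which presence
#'   (any abundance > 0) is taken.
#' @return data.frame with `combination` (group names joined by `&`) and
#'   `count`; counts sum to the number of distinct OTUs present anywhere.
#' @export
sharing_counts <- function(groups) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop_input("groups must be a named list")
  sets <- lapply(groups, function(g) {
    if (is.character(g)) return(unique(g))
    m <- as_abundance_matrix(g, "samples")
    colnames(m)[colSums(m > 0) > 0]
  })
  all_otus <- unique(unlist(sets))
  sig <- vapply(all_otus, function(o)
    paste(names(sets)[vapply(sets, function(s) o %in% s, logical(1))],
          collapse = "&"), character(1))
  g <- names(sets)
  combos <- unlist(lapply(seq_along(g), function(k)
    apply(utils::combn(g, k), 2, paste, collapse = "&")))
  data.frame(combination = combos,
             count = vapply(combos, function(cb) sum(sig == cb), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect modules of OTUs with similar abundance patterns
#'
#' Clusters OTU abundance profiles by UPGMA on Bray-Curtis dissimilarity and
#' cuts the tree into `k` modules (or at height `h`). Module labels are
#' renumbered by the first sample (in table order) at which any member OTU
#' is present, so module I appears first along the sample axis.
#'
#' @param x a `"trf_otu_table"` or samples x OTUs matrix.
#' @param k number of modules (default 4); ignored when `h` is given.
#' @param h optional cut height.
#' @return Named integer vector mapping OTU id to module number.
#' @export
detect_modules <- function(x, k = 4, h = NULL) {
  m <- as_abundance_matrix(x, "samples")
  if (ncol(m) < 2) stop_input("at least two OTUs are required")
  if (is.null(h) && k > ncol(m)) stop_input("k exceeds the number of OTUs")
  d <- bray_curtis(m, axis = "otus")
  hc <- hierarchical_cluster(d)
  cl <- if (is.null(h)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
  first_sample <- vapply(split(names(cl), cl), function(ids) {
    sub <- m[, ids, drop = FALSE]
    present <- which(rowSums(sub > 0) > 0)
    if (length(present)) min(present) else Inf
  }, numeric(1))
  relabel <- stats::setNames(rank(first_sample, ties.method = "first"),
                             names(first_sample))
  out <- as.integer(relabel[as.character(cl)])
  names(out) <- names(cl)
  out
}
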