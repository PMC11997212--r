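#' Bray-Curtis dissimilarity of a community matrix
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)`, optionally after a
#' `log(1 + x)` transformation that damps the influence of highly vocal
#' (abundant) species. Two or more all-zero site rows make pairwise
#' distances undefined and raise an error naming the sites.
#'
#' @param X nonnegative site-by-species matrix.
#' @param log1p apply `log(1 + x)` first (default `TRUE`).
#' @return a `dist` object with values in \[0, 1\].
#' @export
bray_curtis <- function(X, log1p = TRUE) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("community matrix must be nonnegative")
  zero <- rowSums(X) == 0
  if (sum(zero) >= 2)
    stop("distance undefined between all-zero sites: ",
         paste(rownames(X)[zero], collapse = ", "))
  if (log1p) X <- log1p(X)
  vegan::vegdist(X, method = "bray")
}

#' Presence-absence transformation and Jaccard distance
#'
#' @param X nonnegative site-by-species matrix.
#' @return `to_presence_absence`: binary matrix `(x > 0)`.
#' @export
to_presence_absence <- function(X) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("community matrix must be nonnegative")
  (X > 0) + 0
}

#' @rdname to_presence_absence
#' @param Xb binary site-by-species matrix.
#' @return `jaccard_distance`: a `dist` of `(b + c) / (a + b + c)` where `a`
#'   counts shared presences and `b`, `c` the presences unique to each site.
#' @export
jaccard_distance <- function(Xb) {
  Xb <- as.matrix(Xb)
  if (!all(Xb %in% c(0, 1))) stop("matrix must be binary; use to_presence_absence()")
  zero <- rowSums(Xb) == 0
  if (sum(zero) >= 2)
    stop("distance undefined between all-zero sites: ",
         paste(rownames(Xb)[zero], collapse = ", "))
  vegan::vegdist(Xb, method = "jaccard")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Minimises Kruskal stress-1 over `n_starts` random starts (engine:
#' isotonic-regression NMDS as implemented in vegan's `monoMDS`, driven by
#' `metaMDS`), keeping the lowest-stress solution; convergence is declared
#' when independent starts agree under Procrustes. No data transformation is
#' applied inside (`autotransform` off): any log1p happens explicitly in the
#' distance step. Final scores are centred and principal-axis rotated.
#'
#' @param D a `dist` object.
#' @param k number of ordination dimensions (default 2; must be < n - 1).
#' @param n_starts random starts (default 20).
#' @param maxit iteration cap per start.
#' @param seed optional integer seed (the ordination is stochastic).
#' @return object of class `nmds_ordination`: `points` (n x k, centred),
#'   `stress` (in \[0, 1\]), `converged`, `n_starts`, `seed`, and the
#'   underlying engine object in `engine`.
#' @export
nmds <- function(D, k = 2, n_starts = 20, maxit = 200, seed = NULL) {
  stopifnot(inherits(D, "dist"))
  n <- attr(D, "Size")
  if (k >= n - 1) stop("k must be smaller than n - 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- suppressWarnings(vegan::metaMDS(D, k = k, try = n_starts,
                                       trymax = n_starts, maxit = maxit,
                                       trace = 0, autotransform = FALSE,
                                       wascores = FALSE))
  structure(list(points = m$points, stress = m$stress,
                 converged = isTRUE(m$converged > 0) || isTRUE(m$converged),
                 n_starts = n_starts, seed = seed, engine = m),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat("<nmds_ordination> ", nrow(x$points), " sites in ", ncol(x$points),
      " dimensions; stress = ", round(x$stress, 4),
      if (!x$converged) " (no convergent solution)", "\n", sep = "")
  invisible(x)
}

#' @export
plot.nmds_ordination <- function(x, ...) {
  graphics::plot(x$points, asp = 1, xlab = "NMDS1", ylab = "NMDS2", ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey")
  invisible(x)
}

#' Stress as a function of the iteration budget for one NMDS start
#'
#' Runs the isotonic-regression NMDS engine from a fixed initial
#' configuration with increasing iteration caps and reports the stress at
#' each cap; stress is non-increasing along the path because every extra
#' iteration can only improve (or retain) the configuration.
#'
#' @param D a `dist` object.
#' @param k dimensions.
#' @param init n x k matrix of starting coordinates.
#' @param maxits increasing vector of iteration caps.
#' @return numeric vector of stress values, one per cap.
#' @export
nmds_stress_path <- function(D, k = 2, init, maxits = c(1, 2, 5, 10, 25, 50,
                                                        100, 200)) {
  stopifnot(inherits(D, "dist"), is.matrix(init), ncol(init) == k)
  vapply(maxits, function(m)
    vegan::monoMDS(D, y = init, k = k, maxit = m, smin = 0, sratmax = 1,
                   sfgrmin = 0)$stress, 0)
}

#' Weighted-average species scores for an ordination
#'
#' Species are placed at the abundance-weighted (here VAR-weighted) average
#' of the site scores at which they occur.
#'
#' @param ord an `nmds_ordination`.
#' @param X the site-by-species matrix the ordination distances came from.
#' @return matrix of species scores (species x k).
#' @export
species_scores <- function(ord, X) {
  stopifnot(inherits(ord, "nmds_ordination"))
  vegan::wascores(ord$points, as.matrix(X))
}

#' Rigidly rotate an ordination to align a variable with the first axis
#'
#' Applies the rotation (a rigid motion: stress and all inter-point
#' distances are unchanged) that makes the fitted direction of the given
#' site-level variable coincide with `(1, 0)`; used to make the first axis
#' read as the vegetation gradient.
#'
#' @param ord a 2-d `nmds_ordination`.
#' @param v numeric site-level variable (e.g. buffer NDVI).
#' @return the rotated `nmds_ordination`.
#' @export
rotate_to_variable <- function(ord, v) {
  stopifnot(inherits(ord, "nmds_ordination"))
  if (ncol(ord$points) != 2) stop("rotation requires a 2-d ordination")
  if (stats::var(v) == 0) stop("cannot rotate to a zero-variance variable")
  r <- vegan::MDSrotate(ord$engine, v)
  out <- ord
  out$engine <- r
  out$points <- r$points
  out
}

#' Fit environmental vectors and factor centroids onto ordination scores
#'
#' Continuous variables are regressed on the site scores; the reported
#' direction cosines are unit-norm and r-squared is the squared correlation
#' between the variable and its projection. Factors are summarised by level
#' centroids with a within/total sum-of-squares r-squared. Significance is
#' assessed by permuting the variable's rows. Constant variables get r2 = 0
#' and p = 1 with a warning instead of an error.
#'
#' @param ord an `nmds_ordination` (or a score matrix).
#' @param env data frame of environmental variables (numeric and/or factor).
#' @param n_perm permutations (default 999).
#' @param seed optional integer seed.
#' @return list with `vectors` (data frame: variable, one direction column
#'   per axis, `r2`, `p`), `factors` (data frame of level centroids) and
#'   `factor_r2` (data frame: variable, `r2`, `p`).
#' @export
env_fit <- function(ord, env, n_perm = 999, seed = NULL) {
  sc <- if (inherits(ord, "nmds_ordination")) ord$points else as.matrix(ord)
  env <- as.data.frame(env)
  if (!is.null(seed)) set.seed(as.integer(seed))
  isnum <- vapply(env, is.numeric, TRUE)
  const <- vapply(seq_along(env), function(j)
    isnum[j] && stats::var(env[[j]]) == 0, TRUE)
  if (any(const)) {
    warning("constant environmental variables get r2 = 0, p = 1: ",
            paste(names(env)[const], collapse = ", "))
  }
  fit_env <- env[!const]
  ef <- vegan::envfit(sc, fit_env, permutations = n_perm)
  k <- ncol(sc)
  vectors <- NULL
  if (!is.null(ef$vectors) && nrow(ef$vectors$arrows) > 0) {
    arr <- ef$vectors$arrows      # already unit-norm direction cosines
    vectors <- data.frame(variable = rownames(arr), arr,
                          r2 = ef$vectors$r, p = ef$vectors$pvals,
                          row.names = NULL, stringsAsFactors = FALSE)
  }
  factors <- factor_r2 <- NULL
  if (!is.null(ef$factors) && length(ef$factors$r) > 0) {
    factors <- data.frame(level = rownames(ef$factors$centroids),
                          ef$factors$centroids, row.names = NULL,
                          stringsAsFactors = FALSE)
    factor_r2 <- data.frame(variable = names(ef$factors$r),
                            r2 = as.numeric(ef$factors$r),
                            p = as.numeric(ef$factors$pvals),
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  if (any(const)) {
    zero <- data.frame(variable = names(env)[const],
                       matrix(0, sum(const), k,
                              dimnames = list(NULL, colnames(sc))),
                       r2 = 0, p = 1, row.names = NULL,
                       stringsAsFactors = FALSE)
    vectors <- if (is.null(vectors)) zero else rbind(vectors, zero)
  }
  list(vectors = vectors, factors = factors, factor_r2 = factor_r2)
}

#' Map raw habitat-preference labels to analysis classes
#'
#' Applies the habitat reassignments used for community annotation: rock and
#' coastal preferences become human-modified (urban species often originate
#' from cliff habitats, and inland cities have no coast); riverine and
#' wetland collapse to aquatic; grassland and shrubland collapse to open;
#' forest, woodland, human-modified, aquatic and open pass through. Labels
#' are matched case-insensitively, tolerating space/underscore/hyphen
#' variants.
#'
#' @param traits data frame with columns `species` and `habitat` (raw
#'   labels, AVONET-style).
#' @param community_species optional character vector; every species in it
#'   must be present in `traits`, otherwise an error lists the missing ones.
#' @return named character vector: species -> habitat class.
#' @export
assign_habitat <- function(traits, community_species = NULL) {
  stopifnot(all(c("species", "habitat") %in% names(traits)))
  if (!is.null(community_species)) {
    miss <- setdiff(community_species, traits$species)
    if (length(miss))
      stop("species missing from the trait table: ",
           paste(miss, collapse = ", "))
  }
  norm <- gsub("[ _-]+", "-", tolower(trimws(traits$habitat)))
  map <- c("rock" = "human-modified", "coastal" = "human-modified",
           "riverine" = "aquatic", "wetland" = "aquatic",
           "grassland" = "open", "shrubland" = "open",
           "forest" = "forest", "woodland" = "woodland",
           "human-modified" = "human-modified", "aquatic" = "aquatic",
           "open" = "open")
  unknown <- setdiff(unique(norm), names(map))
  if (length(unknown))
    stop("unknown habitat labels: ", paste(unknown, collapse = ", "))
  stats::setNames(unname(map[norm]), traits$species)
}

#' Procrustes superimposition of two ordinations with permutation test
#'
#' After centring and unit scaling, finds the orthogonal rotation of the
#' second configuration onto the first that minimises the residual sum of
#' squares `m2`; the Procrustes correlation is `t = sqrt(1 - m2)`.
#' Significance comes from a row-permutation test (PROTEST).
#'
#' @param A,B score matrices with matching rows.
#' @param n_perm permutations (default 999).
#' @param seed optional integer seed.
#' @return list with `m2`, `t`, `p`.
#' @export
procrustes_protest <- function(A, B, n_perm = 999, seed = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("configurations must have the same rows")
  if (all(apply(A, 2, stats::var) == 0) || all(apply(B, 2, stats::var) == 0))
    stop("degenerate (rank-0) configuration")
  if (!is.null(seed)) set.seed(as.integer(seed))
  pr <- vegan::protest(A, B, permutations = n_perm)
  list(m2 = pr$ss, t = pr$t0, p = pr$signif)
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with a one-sided
#' p-value from simultaneous row/column permutations of the second matrix.
#'
#' @param D1,D2 `dist` objects over the same sites.
#' @param n_perm permutations (default 999).
#' @param seed optional integer seed.
#' @return list with `r`, `p`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = NULL) {
  stopifnot(inherits(D1, "dist"), inherits(D2, "dist"))
  if (attr(D1, "Size") != attr(D2, "Size"))
    stop("distance matrices differ in size")
  l1 <- attr(D1, "Labels"); l2 <- attr(D2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("distance matrices are over different site sets")
  if (!is.null(seed)) set.seed(as.integer(seed))
  mt <- vegan::mantel(D1, D2, permutations = n_perm)
  list(r = as.numeric(mt$statistic), p = mt$signif)
}
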