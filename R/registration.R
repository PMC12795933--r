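# Fully automatic surface registration: voxel downsampling, covariance
# normals, FPFH descriptors, mutual correspondence matching, robust global
# alignment (truncated least squares via graduated non-convexity with
# maximal-clique inlier pruning), and ICP refinement.

#' Registration result
#'
#' @param transform estimated model-to-scene [rigid_transform()].
#' @param inlier_count number of inlier correspondences (global stage) or
#'   matched points (ICP).
#' @param inlier_rmse_mm RMS residual over inliers (mm).
#' @param overlap_fraction fraction of transformed model points within the
#'   overlap distance of the scene (`NA` until assessed).
#' @param success verdict of the numeric failure check.
#' @param stage `"global"` or `"refined"`.
#' @param reason failure reason code (`""` on success).
#' @param rmse_history per-iteration RMSE sequence (ICP).
#' @return A `registration_result`.
#' @export
registration_result <- function(transform, inlier_count = 0L,
                                inlier_rmse_mm = NA_real_,
                                overlap_fraction = NA_real_,
                                success = FALSE, stage = "global",
                                reason = "", rmse_history = numeric(0)) {
  structure(list(transform = transform, inlier_count = as.integer(inlier_count),
                 inlier_rmse_mm = inlier_rmse_mm,
                 overlap_fraction = overlap_fraction, success = success,
                 stage = stage, reason = reason, rmse_history = rmse_history),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> stage", x$stage,
      if (isTRUE(x$success)) "SUCCESS" else paste("FAILURE", x$reason),
      sprintf(" rmse %.3f mm, overlap %.2f, %d inliers\n",
              x$inlier_rmse_mm, x$overlap_fraction, x$inlier_count))
  invisible(x)
}

#' Voxel-grid downsampling of a point cloud
#'
#' At most one output point per occupied cubic voxel of edge `s_mm`, at the
#' centroid of that voxel's points; normals are averaged and renormalised.
#' Output voxels are ordered by their grid key, so the result is
#' deterministic and independent of input ordering.
#'
#' @param cloud a nonempty `point_cloud`.
#' @param s_mm voxel edge length (mm).
#' @return The downsampled `point_cloud`.
#' @export
downsample_voxel <- function(cloud, s_mm) {
  stopifnot(is_point_cloud(cloud), s_mm > 0)
  p <- cloud$points
  if (nrow(p) == 0) stop("empty cloud")
  lo <- apply(p, 2, min)
  key <- floor(sweep(p, 2, lo) / s_mm)
  kstr <- paste(key[, 1], key[, 2], key[, 3])
  grp <- match(kstr, sort(unique(kstr)))
  cnt <- tabulate(grp)
  cen <- rowsum(p, grp) / cnt
  nrm <- NULL
  if (!is.null(cloud$normals)) {
    nrm <- rowsum(cloud$normals, grp) / cnt
    len <- sqrt(rowSums(nrm^2))
    len[len < 1e-12] <- 1
    nrm <- nrm / len
  }
  point_cloud(cen, nrm)
}

#' Estimate oriented normals from local covariance
#'
#' The normal at each point is the smallest-eigenvalue eigenvector of its
#' k-neighbourhood covariance. With a known `viewpoint` (e.g. the depth
#' sensor origin) each normal is oriented toward it. Without one,
#' orientation is made consistent by propagation over the minimum spanning
#' tree of the k-nearest-neighbour graph (flipping children against their
#' parent), and the global sign is fixed by a support-point vote: at the
#' extreme point of the cloud along any direction the outward normal must
#' have a positive component along it. This disambiguates both closed
#' surfaces and open shells (a partial face scan). Degenerate
#' neighbourhoods are flagged in the `valid` attribute.
#'
#' @param cloud a `point_cloud` with at least `k` points.
#' @param k number of neighbours.
#' @param viewpoint optional orientation viewpoint (world mm).
#' @return The `point_cloud` with `normals` set and a `valid` attribute.
#' @export
estimate_normals <- function(cloud, k = 30, viewpoint = NULL) {
  stopifnot(is_point_cloud(cloud))
  n <- nrow(cloud$points)
  if (n < k) stop("cloud has fewer than k points")
  ctr <- colMeans(cloud$points)
  r <- cpp_estimate_normals(cloud$points, as.integer(k), ctr)
  N <- r$normals
  if (!is.null(viewpoint)) {
    to_vp <- sweep(-cloud$points, 2, -as.numeric(viewpoint))  # viewpoint - p
    flip <- rowSums(N * to_vp) < 0
    N[flip, ] <- -N[flip, ]
  } else {
    kg <- min(10L, n - 1L)
    nn <- cpp_knn(cloud$points, cloud$points, kg + 1L)
    from <- rep(seq_len(n), kg)
    to <- as.integer(nn$idx[, -1])
    w <- 1 - abs(rowSums(N[from, , drop = FALSE] * N[to, , drop = FALSE]))
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    igraph::E(g)$weight <- w
    g <- igraph::mst(g)
    ord <- igraph::bfs(g, root = 1, unreachable = TRUE, father = TRUE)
    parents <- as.integer(ord$father)
    for (v in as.integer(ord$order)) {
      p <- parents[v]
      if (!is.na(p) && sum(N[v, ] * N[p, ]) < 0) N[v, ] <- -N[v, ]
    }
    dirs <- icosphere(1)$vertices  # 42 probe directions
    proj <- cloud$points %*% t(dirs)
    sup <- apply(proj, 2, which.max)
    vote <- sum(sign(rowSums(N[sup, , drop = FALSE] * dirs)))
    if (vote < 0) N <- -N
  }
  out <- point_cloud(cloud$points, N)
  attr(out, "valid") <- r$valid
  out
}

#' Fast point feature histograms (FPFH)
#'
#' 33-bin rotation-invariant descriptors (3 x 11 histograms of the
#' normal-angle triplet over radius neighbourhoods, with the standard
#' distance-weighted neighbour accumulation). Isolated points receive a
#' zero histogram.
#'
#' @param cloud a `point_cloud` with normals.
#' @param radius_mm neighbourhood radius (mm).
#' @return A `feature_set`: list with `keypoints` and `descriptors` (n x 33).
#' @export
compute_fpfh <- function(cloud, radius_mm = 10) {
  stopifnot(is_point_cloud(cloud), !is.null(cloud$normals), radius_mm > 0)
  desc <- cpp_fpfh(cloud$points, cloud$normals, radius_mm)
  structure(list(keypoints = cloud, descriptors = desc), class = "feature_set")
}

#' Match features by mutual nearest neighbours
#'
#' Nearest neighbours in the 33-dimensional descriptor space, kept only
#' when mutual; pairs are ordered by descriptor distance and optionally
#' capped. Zero (invalid) histograms never match. With
#' `saliency_frac < 1` only the most distinctive descriptors on each side
#' (largest L1 distance from the cloud's mean histogram) take part:
#' near-flat regions produce near-identical histograms whose spurious
#' mutual matches otherwise drown the informative ones.
#'
#' @param src,dst `feature_set` objects.
#' @param mutual require mutual nearest neighbours.
#' @param max_pairs keep at most this many best pairs.
#' @param saliency_frac fraction of most-distinctive keypoints retained per
#'   side before matching (1 = all).
#' @return A `correspondence_set`: `pairs` (k x 2 indices), `src`, `dst`.
#' @export
match_correspondences <- function(src, dst, mutual = TRUE, max_pairs = Inf,
                                  saliency_frac = 1) {
  stopifnot(inherits(src, "feature_set"), inherits(dst, "feature_set"),
            saliency_frac > 0, saliency_frac <= 1)
  A <- src$descriptors; B <- dst$descriptors
  ok_a <- rowSums(A) > 0; ok_b <- rowSums(B) > 0
  if (!any(ok_a) || !any(ok_b)) stop("no valid descriptors to match")
  if (saliency_frac < 1) {
    salient <- function(desc, ok) {
      mu <- colMeans(desc[ok, , drop = FALSE])
      s <- rowSums(abs(sweep(desc, 2, mu)))
      ok & s >= quantile(s[ok], 1 - saliency_frac)
    }
    ok_a <- salient(A, ok_a)
    ok_b <- salient(B, ok_b)
  }
  ia <- which(ok_a); ib <- which(ok_b)
  D2 <- outer(rowSums(A[ia, , drop = FALSE]^2), rowSums(B[ib, , drop = FALSE]^2), `+`) -
    2 * tcrossprod(A[ia, , drop = FALSE], B[ib, , drop = FALSE])
  fw <- max.col(-D2, ties.method = "first")
  pairs <- cbind(ia, ib[fw])
  d <- D2[cbind(seq_along(ia), fw)]
  if (mutual) {
    bw <- max.col(-t(D2), ties.method = "first")
    keep <- bw[fw] == seq_along(ia)
    pairs <- pairs[keep, , drop = FALSE]
    d <- d[keep]
  }
  if (nrow(pairs) == 0) stop("zero feature correspondences")
  ord <- order(d, pairs[, 1])
  pairs <- pairs[ord, , drop = FALSE]
  if (is.finite(max_pairs) && nrow(pairs) > max_pairs)
    pairs <- pairs[seq_len(max_pairs), , drop = FALSE]
  structure(list(pairs = unname(pairs), src = src$keypoints, dst = dst$keypoints),
            class = "correspondence_set")
}

# Decoupled TLS pose from clique correspondences: rotation by GNC-TLS on
# translation-rotation-invariant difference vectors (mu annealed from the
# max residual by factor 1.4 until the surrogate reaches the TLS cost),
# then per-component TLS translation by adaptive voting.
gnc_tls_pose <- function(Sc, Dc, noise_bound_mm) {
  m <- nrow(Sc)
  prs <- utils::combn(m, 2)
  if (ncol(prs) > 4000) prs <- prs[, seq_len(4000), drop = FALSE]
  a <- Sc[prs[2, ], , drop = FALSE] - Sc[prs[1, ], , drop = FALSE]
  b <- Dc[prs[2, ], , drop = FALSE] - Dc[prs[1, ], , drop = FALSE]
  cbar <- 2 * noise_bound_mm
  R <- kabsch(a, b, vectors = TRUE)$R
  resid <- sqrt(rowSums((b - a %*% t(R))^2))
  rmax2 <- max(resid^2, cbar^2 * (1 + 1e-9))
  mu <- cbar^2 / (2 * rmax2 - cbar^2)
  for (it in 1:64) {
    r2 <- resid^2
    w <- ifelse(r2 <= (mu / (mu + 1)) * cbar^2, 1,
                ifelse(r2 >= ((mu + 1) / mu) * cbar^2, 0,
                       cbar * sqrt(mu * (mu + 1)) / pmax(resid, 1e-12) - mu))
    if (sum(w) < 1e-9) break
    R <- kabsch(a, b, w = w, vectors = TRUE)$R
    resid <- sqrt(rowSums((b - a %*% t(R))^2))
    if (all(w < 1e-3 | w > 1 - 1e-3) && it > 3) break
    mu <- mu * 1.4
  }
  V <- Dc - Sc %*% t(R)
  tvec <- vapply(1:3, function(c2) {
    v <- V[, c2]
    votes <- vapply(v, function(x) sum(abs(v - x) <= noise_bound_mm), 0L)
    consensus <- abs(v - v[which.max(votes)]) <= noise_bound_mm
    mean(v[consensus])
  }, 0)
  list(R = R, t = tvec)
}

# Weighted Kabsch/Horn closed-form alignment. When `vectors = TRUE` the
# inputs are direction vectors and only the rotation is estimated.
kabsch <- function(src, dst, w = NULL, vectors = FALSE) {
  if (is.null(w)) w <- rep(1, nrow(src))
  sw <- sum(w)
  if (vectors) {
    H <- crossprod(src * w, dst)
    cs <- cd <- c(0, 0, 0)
  } else {
    cs <- colSums(src * w) / sw
    cd <- colSums(dst * w) / sw
    H <- crossprod(sweep(src, 2, cs) * w, sweep(dst, 2, cd))
  }
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cd - as.numeric(R %*% cs))
}

#' Robust global registration from putative correspondences
#'
#' Decoupled truncated-least-squares estimation with scale fixed at 1
#' (rigid anatomy): (1) translation-rotation-invariant measurement pairs
#' prune gross outliers through the maximal clique of the compatibility
#' graph (edge when `abs(||dsrc|| - ||ddst||) <= 2 * noise_bound_mm`);
#' (2) rotation by graduated non-convexity over the truncated-least-squares
#' cost; (3) translation by per-component truncated-least-squares voting;
#' finally the closed-form alignment is re-fit on the consensus inliers.
#'
#' @param corr a `correspondence_set` with at least 3 pairs.
#' @param noise_bound_mm inlier noise bound (mm).
#' @return A `registration_result` (stage `"global"`).
#' @export
global_register <- function(corr, noise_bound_mm = 3) {
  stopifnot(inherits(corr, "correspondence_set"), noise_bound_mm > 0)
  k <- nrow(corr$pairs)
  if (k < 3) stop("need at least 3 correspondences")
  S <- corr$src$points[corr$pairs[, 1], , drop = FALSE]
  D <- corr$dst$points[corr$pairs[, 2], , drop = FALSE]

  # 1. compatibility graph + maximal cliques (exact branch and bound)
  ds <- as.matrix(stats::dist(S))
  dd <- as.matrix(stats::dist(D))
  compat <- abs(ds - dd) <= 2 * noise_bound_mm
  diag(compat) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(compat, mode = "undirected")
  igraph::V(g)$name <- as.character(seq_len(k))
  # near-symmetric surfaces support competing correspondence structures
  # whose cliques can outsize the true one; deflation (remove each found
  # clique's nodes and re-search) surfaces one clique per structure, and
  # the candidates are ranked by consensus over the full pair set
  cliques <- list()
  g2 <- g
  for (rep_i in 1:4) {
    cl2 <- igraph::largest_cliques(g2)
    if (length(cl2) == 0) break
    ids <- sort(as.integer(names(cl2[[1]])))
    if (length(ids) < 3) break
    cliques[[length(cliques) + 1L]] <- ids
    g2 <- igraph::delete_vertices(g2, as.character(ids))
    if (igraph::vcount(g2) < 3) break
  }
  if (length(cliques) == 0)
    stop("largest compatibility clique smaller than 3")
  cands <- list()
  for (clique in cliques) {
    sol <- gnc_tls_pose(S[clique, , drop = FALSE], D[clique, , drop = FALSE],
                        noise_bound_mm)
    resid_all <- sqrt(rowSums((D - sweep(S %*% t(sol$R), 2, -sol$t))^2))
    cands[[length(cands) + 1L]] <- list(R = sol$R, t = sol$t,
                                        n_cons = sum(resid_all <= noise_bound_mm))
  }
  cands <- cands[order(-vapply(cands, `[[`, 0, "n_cons"))]
  best <- cands[[1]]
  R <- best$R; tvec <- best$t

  # final consensus refit with the closed form, over all correspondences
  resid3 <- sqrt(rowSums((D - sweep(S %*% t(R), 2, -tvec))^2))
  inl <- resid3 <= pmax(noise_bound_mm, 1e-9)
  if (sum(inl) >= 3) {
    fit <- kabsch(S[inl, , drop = FALSE], D[inl, , drop = FALSE])
    R <- fit$R; tvec <- fit$t
    resid3 <- sqrt(rowSums((D - sweep(S %*% t(R), 2, -tvec))^2))
    inl <- resid3 <= pmax(noise_bound_mm, 1e-9)
  }
  rmse <- if (any(inl)) sqrt(mean(resid3[inl]^2)) else NA_real_
  out <- registration_result(rigid_transform(R, tvec),
                             inlier_count = sum(inl), inlier_rmse_mm = rmse,
                             success = TRUE, stage = "global")
  # distinct candidate poses (consensus-ordered) for downstream
  # hypothesis verification against the actual surfaces
  keep <- list()
  for (cn in cands) {
    dup <- any(vapply(keep, function(k)
      rotation_angle_deg(cn$R %*% t(k$R)) < 5 &&
        sqrt(sum((cn$t - k$t)^2)) < 10, TRUE))
    if (!dup) keep[[length(keep) + 1L]] <- cn
  }
  out$candidates <- lapply(keep, function(k) rigid_transform(k$R, k$t))
  out
}

#' Iterative closest point refinement
#'
#' Alternates nearest-neighbour correspondence (within `d_max_mm`, lowest
#' index on ties) with a closed-form point-to-point update or a linearised
#' point-to-plane update (default; requires scene normals). The reported
#' RMSE sequence is the matched-pair RMS distance at each correspondence
#' step, which is non-increasing for point-to-point ICP on full-overlap
#' clouds.
#'
#' @param model,scene `point_cloud`s (scene with normals for point-to-plane).
#' @param init initial model-to-scene [rigid_transform()].
#' @param method `"point_to_plane"` or `"point_to_point"`.
#' @param d_max_mm correspondence rejection distance (mm).
#' @param tol relative RMSE change for convergence.
#' @param max_iter iteration cap.
#' @return A `registration_result` (stage `"refined"`); a scene with no
#'   correspondences at `init` yields `success = FALSE`, not an error.
#' @export
refine_icp <- function(model, scene, init = rt_identity(),
                       method = c("point_to_plane", "point_to_point"),
                       d_max_mm = 10, tol = 1e-6, max_iter = 50) {
  method <- match.arg(method)
  stopifnot(is_point_cloud(model), is_point_cloud(scene),
            is_rigid_transform(init))
  if (nrow(model$points) == 0 || nrow(scene$points) == 0)
    stop("empty cloud")
  if (method == "point_to_plane" && is.null(scene$normals))
    stop("point_to_plane requires scene normals")
  T_cur <- init
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    P <- apply_transform(T_cur, model$points)
    nn <- cpp_nn1(scene$points, P)
    keep <- nn$dist <= d_max_mm
    if (!any(keep)) {
      if (it == 1)
        return(registration_result(T_cur, 0L, NA_real_, 0,
                                   success = FALSE, stage = "refined",
                                   reason = "no_correspondences"))
      break
    }
    rmse <- sqrt(mean(nn$dist[keep]^2))
    hist <- c(hist, rmse)
    p <- P[keep, , drop = FALSE]
    q <- scene$points[nn$idx[keep], , drop = FALSE]
    if (method == "point_to_point") {
      delta <- kabsch(p, q)
    } else {
      nrm <- scene$normals[nn$idx[keep], , drop = FALSE]
      aa <- cbind(p[, 2] * nrm[, 3] - p[, 3] * nrm[, 2],
                  p[, 3] * nrm[, 1] - p[, 1] * nrm[, 3],
                  p[, 1] * nrm[, 2] - p[, 2] * nrm[, 1], nrm)
      bb <- rowSums((q - p) * nrm)
      x <- tryCatch(solve(crossprod(aa), crossprod(aa, bb)),
                    error = function(e) matrix(0, 6, 1))
      ang <- sqrt(sum(x[1:3]^2))
      Rd <- if (ang < 1e-12) diag(3) else rot_axis_angle(x[1:3], ang)
      delta <- rigid_transform(Rd, x[4:6])
    }
    T_new <- rt_compose(delta, T_cur)
    if (rmse < 1e-9) { T_cur <- T_new; break }
    if (length(hist) > 1) {
      prev <- hist[length(hist) - 1]
      if (abs(prev - rmse) <= tol * max(prev, 1e-12)) { T_cur <- T_new; break }
    }
    T_cur <- T_new
  }
  P <- apply_transform(T_cur, model$points)
  nn <- cpp_nn1(scene$points, P)
  keep <- nn$dist <= d_max_mm
  rmse <- if (any(keep)) sqrt(mean(nn$dist[keep]^2)) else NA_real_
  registration_result(T_cur, sum(keep), rmse,
                      overlap_fraction = mean(keep),
                      success = TRUE, stage = "refined",
                      rmse_history = hist)
}

#' Fully automatic reference-to-scene registration
#'
#' The complete markerless cascade: sample the reference surface, voxel
#' downsample both clouds, estimate normals, compute FPFH features, match
#' mutual correspondences, robust global alignment, then ICP refinement.
#' The numeric failure check (replacing an operator's visual inspection)
#' declares success iff the ICP inlier RMSE is at most `rmse_max_mm` AND
#' the fraction of transformed model points within `overlap_d_mm` of the
#' scene is at least `overlap_min`.
#'
#' @param reference the reference skin model (`triangle_mesh`).
#' @param scene the live depth point cloud (`point_cloud`).
#' @param config registration parameter list; defaults from
#'   [default_config()]`$registration`, individual entries overridable.
#' @return A `registration_result` (stage `"refined"`); upstream failures
#'   are reported as `success = FALSE` with a reason code.
#' @export
register_pipeline <- function(reference, scene, config = list()) {
  stopifnot(is_triangle_mesh(reference), is_point_cloud(scene))
  cfg <- utils::modifyList(default_config()$registration, config)
  fail <- function(reason) registration_result(rt_identity(), success = FALSE,
                                               stage = "refined", reason = reason)
  if (nrow(scene$points) < cfg$normal_k) return(fail("scene_too_small"))
  res <- tryCatch({
    # both clouds get the same covariance normal estimator so their FPFH
    # statistics are comparable; orientation is made consistent per cloud
    ref_cloud <- sample_surface(reference, cfg$model_samples,
                                seed = cfg$sampling_seed)
    model <- downsample_voxel(ref_cloud, cfg$voxel_mm)
    scn <- downsample_voxel(scene, cfg$voxel_mm)
    if (nrow(scn$points) < cfg$normal_k) return(fail("scene_too_small"))
    model <- estimate_normals(model, cfg$normal_k)
    scn <- estimate_normals(scn, cfg$normal_k)
    fs <- compute_fpfh(model, cfg$fpfh_radius_mm)
    fd <- compute_fpfh(scn, cfg$fpfh_radius_mm)
    corr <- match_correspondences(fs, fd, max_pairs = cfg$max_correspondences,
                                  saliency_frac = cfg$saliency_frac)
    glob <- global_register(corr, cfg$noise_bound_mm)
    # hypothesis verification: near-symmetric faces can yield competing
    # global poses; refine each briefly and keep the best surface fit
    cands <- glob$candidates[seq_len(min(length(glob$candidates),
                                         cfg$max_hypotheses))]
    init <- glob$transform
    if (length(cands) > 1) {
      fit <- function(Tc) {
        r <- refine_icp(model, scn, Tc, method = cfg$icp_method,
                        d_max_mm = cfg$icp_d_max_mm, tol = 1e-4, max_iter = 10)
        d <- cpp_nn1(scene$points,
                     apply_transform(r$transform, model$points))$dist
        mean(pmin(d, cfg$overlap_d_mm))  # truncated-distance fitness
      }
      init <- cands[[which.min(vapply(cands, fit, 0))]]
    }
    icp <- refine_icp(model, scn, init, method = cfg$icp_method,
                      d_max_mm = cfg$icp_d_max_mm, tol = cfg$icp_tol,
                      max_iter = cfg$icp_max_iter)
    if (!icp$success && nzchar(icp$reason)) return(icp)
    # verdict against the raw (full-resolution) scene: residuals then
    # reflect surface distance rather than downsampled spacing
    P <- apply_transform(icp$transform, model$points)
    d <- cpp_nn1(scene$points, P)$dist
    ov <- mean(d <= cfg$overlap_d_mm)
    rmse <- if (any(d <= cfg$overlap_d_mm))
      sqrt(mean(d[d <= cfg$overlap_d_mm]^2)) else NA_real_
    ok <- !is.na(rmse) && rmse <= cfg$rmse_max_mm && ov >= cfg$overlap_min
    registration_result(icp$transform, icp$inlier_count, rmse,
                        overlap_fraction = ov, success = ok, stage = "refined",
                        reason = if (ok) "" else "failure_check",
                        rmse_history = icp$rmse_history)
  }, error = function(e) fail(paste0("pipeline_error:", conditionMessage(e))))
  res
}

#' Register with the backup full-head reference model
#'
#' Mirrors the clinical protocol: attempt registration with the face-only
#' reference; on failure, retry exactly once with the full-head model.
#'
#' @param face_ref,full_ref face-only and full-head reference meshes.
#' @param scene the live `point_cloud`.
#' @param config registration parameters (see [register_pipeline()]).
#' @return List with `result`, `attempts` (1 or 2) and `reference_mode`.
#' @export
register_with_fallback <- function(face_ref, full_ref, scene, config = list()) {
  r1 <- register_pipeline(face_ref, scene, config)
  if (r1$success)
    return(list(result = r1, attempts = 1L, reference_mode = "face_only"))
  r2 <- register_pipeline(full_ref, scene, config)
  list(result = r2, attempts = 2L, reference_mode = "full_head")
}
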