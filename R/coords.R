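#' Shape-adapted ventricular coordinates
#'
#' Computes the transmural (t), circumferential (c) and longitudinal (l)
#' coordinates on a labeled LV mesh from Laplace-Dirichlet problems:
#' \itemize{
#'   \item t: endocardium = 0, epicardium = 1;
#'   \item l: basal plane = 1, apical cylinder = 0;
#'   \item c: two half-domain problems with Dirichlet data on the plane
#'     through the anterior side and the long axis; the apical cylinder is
#'     treated as insulating (its tetrahedra are excluded) and c inside it is
#'     taken from the cylindrical angle about the long axis.
#' }
#' The circumferential convention is c = 0 on the anterior split plane,
#' increasing counterclockwise seen from the base, with values in [0, 1) and
#' a single wrap seam at the anterior plane.
#'
#' @param mesh a [tet_mesh()] with `endo`, `epi`, `base` labels and a
#'   non-empty `apex_region`.
#' @param long_axis unit long-axis direction (apex to base); defaults to the
#'   mesh metadata or +z.
#' @param streamline_l if TRUE, replace the longitudinal Laplace field by its
#'   per-streamline arc-length normalization (see [streamline_normalize()]).
#' @param streamline_t same for the transmural field.
#' @return object of class `ventricular_coords`: list with nodal vectors
#'   `t`, `c`, `l` and the raw Laplace solutions.
#' @export
compute_ventricular_coords <- function(mesh, long_axis = NULL,
                                       streamline_l = FALSE,
                                       streamline_t = FALSE) {
  for (lab in c("endo", "epi", "base")) {
    if (is.null(mesh$surfaces[[lab]]) || nrow(mesh$surfaces[[lab]]) == 0L) {
      stop("mesh is missing surface label: ", lab)
    }
  }
  if (is.null(long_axis)) {
    long_axis <- if (!is.null(mesh$meta$long_axis)) mesh$meta$long_axis else c(0, 0, 1)
  }
  long_axis <- long_axis / sqrt(sum(long_axis^2))

  endo_n <- surface_nodes(mesh, "endo")
  epi_n <- surface_nodes(mesh, "epi")
  base_n <- surface_nodes(mesh, "base")
  apex_n <- mesh$apex_region

  sol_t <- solve_laplace(mesh, list(list(nodes = endo_n, value = 0),
                                    list(nodes = setdiff(epi_n, endo_n), value = 1)))
  sol_l <- solve_laplace(mesh, list(list(nodes = base_n, value = 1),
                                    list(nodes = setdiff(apex_n, base_n), value = 0)))

  ## circumferential: work in a frame where the long axis is +z
  R <- axis_frame(long_axis)
  local <- mesh$nodes %*% R           # columns: x', y', z' with z' = long axis
  extent <- max(apply(local, 2L, function(v) diff(range(v))))
  tol <- 1e-6 * extent
  on_plane <- abs(local[, 2L]) < tol
  anterior <- which(on_plane & local[, 1L] > tol)
  posterior <- which(on_plane & local[, 1L] < -tol)
  if (length(anterior) == 0L || length(posterior) == 0L) {
    stop("could not find nodes on the anterior/posterior split plane")
  }
  in_apex <- matrix(mesh$tets %in% apex_n, ncol = 4L)
  apex_tets <- rowSums(in_apex) == 4L
  anterior <- setdiff(anterior, apex_n)
  posterior <- setdiff(posterior, apex_n)
  ## two half-domain problems: the anterior/posterior split plane is a real
  ## boundary face of each half, the apical cylinder insulates
  centroid_y <- (local[mesh$tets[, 1L], 2L] + local[mesh$tets[, 2L], 2L] +
                 local[mesh$tets[, 3L], 2L] + local[mesh$tets[, 4L], 2L]) / 4
  dsets <- list(list(nodes = anterior, value = 0),
                list(nodes = posterior, value = 1))
  sol_up <- solve_laplace(mesh, dsets,
                          exclude_tets = which(centroid_y < 0 | apex_tets))
  sol_dn <- solve_laplace(mesh, dsets,
                          exclude_tets = which(centroid_y > 0 | apex_tets))
  cc <- rep(NA_real_, nrow(mesh$nodes))
  pos_half <- local[, 2L] >= 0
  cc[pos_half] <- sol_up$u[pos_half] / 2
  cc[!pos_half] <- 1 - sol_dn$u[!pos_half] / 2
  cc[anterior] <- 0
  cc[posterior] <- 0.5
  sol_c <- list(upper = sol_up, lower = sol_dn)
  ## apical cylinder and any node detached from the conducting domain:
  ## cylindrical angle about the long axis
  need_angle <- union(apex_n, which(is.na(cc)))
  ang <- atan2(local[need_angle, 2L], local[need_angle, 1L]) / (2 * pi)
  cc[need_angle] <- ang %% 1
  cc <- cc %% 1

  t_field <- pmin(pmax(sol_t$u, 0), 1)
  l_field <- pmin(pmax(sol_l$u, 0), 1)
  if (streamline_t) {
    st <- streamline_normalize(mesh, nodal_gradient(mesh, sol_t$u),
                               terminal = union(endo_n, epi_n))
    t_field <- ifelse(is.na(st), t_field, st)
  }
  if (streamline_l) {
    sl <- streamline_normalize(mesh, nodal_gradient(mesh, sol_l$u),
                               terminal = union(base_n, apex_n))
    l_field <- ifelse(is.na(sl), l_field, sl)
  }
  structure(list(t = t_field, c = cc, l = l_field,
                 laplace = list(t = sol_t, c = sol_c, l = sol_l),
                 long_axis = long_axis),
            class = "ventricular_coords")
}

## orthonormal matrix whose third column is the given axis
axis_frame <- function(axis) {
  w <- axis / sqrt(sum(axis^2))
  seed <- if (abs(w[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2L] * u[3L] - w[3L] * u[2L],
         w[3L] * u[1L] - w[1L] * u[3L],
         w[1L] * u[2L] - w[2L] * u[1L])
  cbind(u, v, w)  # right-handed with column3 = axis (v = axis x u)
}

## nodal gradient of a scalar field (volume-weighted element average)
nodal_gradient <- function(mesh, u, sg = NULL) {
  if (is.null(sg)) sg <- element_shape_gradients(mesh$nodes, mesh$tets)
  elements_to_nodes(mesh, element_gradient(mesh, u, sg), sg)
}

#' Re-orthogonalized local coordinate frames
#'
#' Builds the per-node orthonormal triads (e_t, e_c, e_l) from the gradients
#' of the transmural and longitudinal coordinate fields.  Gram-Schmidt order:
#' e_t (from the transmural gradient, the most reliable direction on thin
#' walls), then e_l (longitudinal gradient orthogonalized against e_t), then
#' e_c = e_l x e_t, which makes the circumferential axis increase
#' counterclockwise seen from the base.
#'
#' @param mesh a [tet_mesh()].
#' @param coords a `ventricular_coords` object.
#' @param fallback optional list with unit vectors `e_t` and/or `e_l` used for
#'   nodes whose gradient degenerates (for instance inside the insulated
#'   apical cylinder, where the longitudinal Dirichlet data is flat).  Without
#'   a fallback a degenerate gradient is an error naming the node.
#' @return object of class `local_frames`: list of (n x 3) matrices
#'   `e_t`, `e_c`, `e_l`.
#' @export
compute_local_frames <- function(mesh, coords, fallback = NULL) {
  sg <- element_shape_gradients(mesh$nodes, mesh$tets)
  gt <- nodal_gradient(mesh, coords$laplace$t$u, sg)
  gl <- nodal_gradient(mesh, coords$laplace$l$u, sg)
  orthonormal_frames(gt, gl, fallback = fallback)
}

#' Gram-Schmidt frame construction from raw direction fields
#'
#' @param g_t raw transmural directions (n x 3).
#' @param g_l raw longitudinal directions (n x 3).
#' @param fallback optional list with `e_t`, `e_l` fallback unit vectors.
#' @param tol relative norm below which a gradient counts as degenerate.
#' @return `local_frames` object.
#' @export
orthonormal_frames <- function(g_t, g_l, fallback = NULL, tol = 1e-10) {
  g_t <- as.matrix(g_t); g_l <- as.matrix(g_l)
  nt <- sqrt(rowSums(g_t^2))
  scale_t <- stats::median(nt[nt > 0])
  bad_t <- nt < tol * max(scale_t, .Machine$double.xmin)
  if (any(bad_t)) {
    if (is.null(fallback$e_t)) {
      stop("degenerate transmural gradient at node(s): ",
           paste(utils::head(which(bad_t), 5L), collapse = ", "))
    }
    g_t[bad_t, ] <- matrix(fallback$e_t, sum(bad_t), 3L, byrow = TRUE)
    nt[bad_t] <- 1
  }
  e_t <- g_t / sqrt(rowSums(g_t^2))
  raw_l <- g_l - rowSums(g_l * e_t) * e_t
  nl <- sqrt(rowSums(raw_l^2))
  scale_l <- stats::median(nl[nl > 0])
  bad_l <- nl < tol * max(scale_l, .Machine$double.xmin)
  if (any(bad_l)) {
    if (is.null(fallback$e_l)) {
      stop("degenerate longitudinal gradient at node(s): ",
           paste(utils::head(which(bad_l), 5L), collapse = ", "))
    }
    fb <- matrix(fallback$e_l, sum(bad_l), 3L, byrow = TRUE)
    fb <- fb - rowSums(fb * e_t[bad_l, , drop = FALSE]) * e_t[bad_l, , drop = FALSE]
    raw_l[bad_l, ] <- fb
  }
  e_l <- raw_l / sqrt(rowSums(raw_l^2))
  e_c <- cbind(e_l[, 2L] * e_t[, 3L] - e_l[, 3L] * e_t[, 2L],
               e_l[, 3L] * e_t[, 1L] - e_l[, 1L] * e_t[, 3L],
               e_l[, 1L] * e_t[, 2L] - e_l[, 2L] * e_t[, 1L])
  structure(list(e_t = e_t, e_c = e_c, e_l = e_l,
                 degenerate = which(bad_t | bad_l)),
            class = "local_frames")
}

#' Streamline arc-length normalization of a coordinate field
#'
#' Traces streamlines of a nodal direction field with a fixed-step RK4
#' integrator from every requested node, both against and along the field,
#' until the trajectory leaves the mesh.  The normalized coordinate is the
#' backward arc length divided by the total streamline length, so each node
#' is normalized by its own streamline (wall-thickness invariant).
#'
#' @param mesh a [tet_mesh()].
#' @param direction_field nodal vectors (n x 3); the gradient of a Laplace
#'   coordinate field in the intended use.
#' @param seed_nodes nodes to trace from (default: all).
#' @param step integration step (mm); default a quarter of the mean edge
#'   length.
#' @param max_steps per-direction step budget; nodes whose streamline does not
#'   terminate within the budget are returned as NA (callers fall back to the
#'   raw Laplace value).
#' @param terminal optional integer vector of node indices marking the
#'   terminal boundary surfaces (e.g. endo + epi wall nodes for the
#'   transmural field).  When given, a trajectory leaving the mesh away from
#'   a terminal surface is slid tangentially back inside and continued
#'   (grazing exits along insulated boundaries are artifacts of the discrete
#'   gradient); without it any exit terminates the streamline.
#' @param slide_budget maximum number of tangential slides per trajectory
#'   before it is flagged as failed.
#' @return numeric vector over all mesh nodes (NA where not traced or
#'   failed), with attribute `failed` listing failed seed nodes.
#' @export
streamline_normalize <- function(mesh, direction_field, seed_nodes = NULL,
                                 step = NULL, max_steps = 2000L,
                                 terminal = NULL, slide_budget = 100L) {
  n <- nrow(mesh$nodes)
  if (is.null(seed_nodes)) seed_nodes <- seq_len(n)
  dirs <- as.matrix(direction_field)
  nv <- sqrt(rowSums(dirs^2))
  if (any(nv == 0)) {
    ## zero vectors cannot be traced through; leave them, interpolation of
    ## neighbors usually still yields a nonzero local direction
    nv[nv == 0] <- 1
  }
  unit <- dirs / nv
  if (is.null(step)) {
    e1 <- mesh$nodes[mesh$tets[, 1L], ] - mesh$nodes[mesh$tets[, 2L], ]
    step <- 0.25 * mean(sqrt(rowSums(e1^2)))
  }

  f_at <- function(q, sgn) {
    v <- interp_at_points(mesh, unit, q)
    inside <- attr(v, "inside")
    v[!inside, ] <- 0
    nrm <- sqrt(rowSums(v^2))
    ok <- nrm > 1e-12
    v[ok, ] <- v[ok, , drop = FALSE] / nrm[ok]
    list(v = sgn * v, inside = inside & ok)
  }
  if (!is.null(terminal)) {
    terminal <- as.integer(terminal)
    h_term <- node_max_edge(mesh)[terminal]
    ## terminal boundary triangles: boundary faces with all nodes terminal
    bt <- boundary_triangles(mesh$tets, mesh$nodes)
    tmask <- matrix(bt %in% terminal, ncol = 3L)
    bt_term <- bt[rowSums(tmask) == 3L, , drop = FALSE]
    ## unit normals and support points of the terminal faces
    ta <- mesh$nodes[bt_term[, 1L], , drop = FALSE]
    tu <- mesh$nodes[bt_term[, 2L], , drop = FALSE] - ta
    tv <- mesh$nodes[bt_term[, 3L], , drop = FALSE] - ta
    tnorm <- cbind(tu[, 2L] * tv[, 3L] - tu[, 3L] * tv[, 2L],
                   tu[, 3L] * tv[, 1L] - tu[, 1L] * tv[, 3L],
                   tu[, 1L] * tv[, 2L] - tu[, 2L] * tv[, 1L])
    tnorm <- tnorm / sqrt(rowSums(tnorm^2))
    ## map terminal node -> incident terminal triangles
    node_tris <- split(rep(seq_len(nrow(bt_term)), 3L), as.vector(bt_term))
    ## plane distance of points q (rows) to faces incident to node nt
    term_plane_dist <- function(q, nt_global) {
      vapply(seq_len(nrow(q)), function(i) {
        tris <- node_tris[[as.character(nt_global[i])]]
        if (is.null(tris)) return(Inf)
        diff <- matrix(q[i, ], nrow = length(tris), ncol = 3L, byrow = TRUE) -
          ta[tris, , drop = FALSE]
        min(abs(rowSums(diff * tnorm[tris, , drop = FALSE])))
      }, 0)
    }
  }
  trace_len <- function(sgn) {
    pos <- mesh$nodes[seed_nodes, , drop = FALSE]
    len <- numeric(length(seed_nodes))
    slides <- integer(length(seed_nodes))
    active <- rep(TRUE, length(seed_nodes))
    done_ok <- rep(FALSE, length(seed_nodes))
    for (it in seq_len(max_steps)) {
      sub <- which(active)
      if (length(sub) == 0L) break
      p <- pos[sub, , drop = FALSE]
      k1 <- f_at(p, sgn)
      k2 <- f_at(p + step / 2 * k1$v, sgn)
      k3 <- f_at(p + step / 2 * k2$v, sgn)
      k4 <- f_at(p + step * k3$v, sgn)
      newp <- p + step / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
      probe <- locate_points(mesh, newp)
      left <- is.na(probe$tet) | !k1$inside
      adv <- sub[!left]
      if (length(adv) > 0L) {
        len[adv] <- len[adv] + step
        pos[adv, ] <- newp[!left, , drop = FALSE]
      }
      stopped <- sub[left]
      if (length(stopped) > 0L) {
        ## bisect towards the boundary along the last straight segment
        lo <- pos[stopped, , drop = FALSE]
        hi <- newp[left, , drop = FALSE]
        for (b in 1:12) {
          mid <- (lo + hi) / 2
          ins <- !is.na(locate_points(mesh, mid)$tet)
          lo[ins, ] <- mid[ins, , drop = FALSE]
          hi[!ins, ] <- mid[!ins, , drop = FALSE]
        }
        travel <- sqrt(rowSums((lo - pos[stopped, , drop = FALSE])^2))
        len[stopped] <- len[stopped] + travel
        pos[stopped, ] <- lo
        if (is.null(terminal)) {
          done_ok[stopped] <- TRUE
          active[stopped] <- FALSE
        } else {
          ## exit near a terminal surface ends the streamline; elsewhere
          ## slide tangentially back inside and continue
          nt <- nearest_node(mesh$nodes[terminal, , drop = FALSE], lo)
          d_node <- sqrt(rowSums((lo - mesh$nodes[terminal[nt], , drop = FALSE])^2))
          d_plane <- term_plane_dist(lo, terminal[nt])
          at_term <- d_node <= 1.5 * h_term[nt] & d_plane <= 0.05 * h_term[nt]
          fin <- stopped[at_term]
          done_ok[fin] <- TRUE
          active[fin] <- FALSE
          sl <- which(!at_term)
          if (length(sl) > 0L) {
            ids <- stopped[sl]
            slides[ids] <- slides[ids] + 1L
            give_up <- slides[ids] > slide_budget
            active[ids[give_up]] <- FALSE   # flagged failed
            keep <- ids[!give_up]
            if (length(keep) > 0L) {
              q <- pos[keep, , drop = FALSE]
              lc <- locate_points(mesh, q)
              ok_in <- !is.na(lc$tet)
              if (any(!ok_in)) { active[keep[!ok_in]] <- FALSE }
              keep <- keep[ok_in]
              if (length(keep) > 0L) {
                lc_t <- lc$tet[ok_in]
                cent <- (mesh$nodes[mesh$tets[lc_t, 1L], , drop = FALSE] +
                         mesh$nodes[mesh$tets[lc_t, 2L], , drop = FALSE] +
                         mesh$nodes[mesh$tets[lc_t, 3L], , drop = FALSE] +
                         mesh$nodes[mesh$tets[lc_t, 4L], , drop = FALSE]) / 4
                q <- pos[keep, , drop = FALSE]
                nvec <- cent - q
                vv <- f_at(q, sgn)$v
                nvec <- nvec - rowSums(nvec * vv) * vv  # keep arc length true
                nn2 <- sqrt(rowSums(nvec^2))
                nn2[nn2 < 1e-12] <- 1
                pos[keep, ] <- q + 0.2 * step * nvec / nn2
              }
            }
          }
        }
      }
    }
    list(len = len, ok = done_ok)
  }
  bwd <- trace_len(-1)
  fwd <- trace_len(+1)
  total <- bwd$len + fwd$len
  u <- rep(NA_real_, n)
  val <- ifelse(total > 0, bwd$len / total, 0)
  ok <- bwd$ok & fwd$ok
  u[seed_nodes[ok]] <- val[ok]
  attr(u, "failed") <- seed_nodes[!ok]
  u
}
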