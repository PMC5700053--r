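#' Functional connectivity (Pearson correlation) matrix
#'
#' Pairwise Pearson correlations between node time series, the standard
#' functional-connectivity summary of resting-state data.
#'
#' @param traj An [trajectory()] (or plain T x N matrix) with `T >= 3` and
#'   no constant node series.
#' @return Symmetric N x N correlation matrix with unit diagonal and node
#'   labels as dimnames.
#' @export
functional_connectivity <- function(traj) {
  m <- if (inherits(traj, "egnb_trajectory")) traj$states else as.matrix(traj)
  if (nrow(m) < 3L) stop("need at least 3 samples for correlations", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("n", seq_len(ncol(m)))
  sds <- apply(m, 2L, stats::sd)
  flat <- which(sds == 0)
  if (length(flat)) {
    stop("constant series have undefined correlations: node(s) ",
         paste(colnames(m)[flat], collapse = ", "), call. = FALSE)
  }
  fc <- stats::cor(m)
  # enforce exact symmetry/unit diagonal against roundoff
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

#' Remove a node (row and column) from a signed connectivity matrix
#'
#' The structural half of an in-silico lesion: the target region and every
#' coupling to or from it are deleted; the original matrix is untouched.
#'
#' @param conn A [signed_connectivity()] matrix.
#' @param node A node label (or integer index).
#' @return The (N-1) x (N-1) [signed_connectivity()] of the survivors.
#' @export
lesion_node <- function(conn, node) {
  labels <- node_labels(conn)
  if (is.character(node)) {
    if (!(node %in% labels)) {
      stop("unknown node label: ", node, call. = FALSE)
    }
    idx <- match(node, labels)
  } else {
    idx <- as.integer(node)
    if (idx < 1L || idx > length(labels)) stop("node index out of range", call. = FALSE)
  }
  keep <- setdiff(seq_along(labels), idx)
  signed_connectivity(as_conn_matrix(conn)[keep, keep, drop = FALSE],
                      labels = labels[keep])
}

#' Pick the lesion target with the highest within-group strength
#'
#' Among the nodes of a group (e.g. a resting-state network), returns the
#' one with the largest total coupling strength to and from the other group
#' members, i.e. `sum_w |a'_{v,w}| + |a'_{w,v}|` over group members
#' `w != v`. Ties are broken by the order in which labels are given.
#'
#' @param conn A [signed_connectivity()] matrix.
#' @param group Non-empty character vector of node labels forming the group.
#' @return The selected node label.
#' @export
select_lesion_target <- function(conn, group) {
  labels <- node_labels(conn)
  if (length(group) == 0L) stop("group must be non-empty", call. = FALSE)
  if (!all(group %in% labels)) {
    stop("unknown group label(s): ",
         paste(setdiff(group, labels), collapse = ", "), call. = FALSE)
  }
  A <- coupling_weights(conn)
  strength <- vapply(group, function(v) {
    others <- setdiff(group, v)
    if (!length(others)) return(0)
    sum(A[v, others]) + sum(A[others, v])
  }, numeric(1))
  group[which.max(strength)]   # which.max takes the first maximum: tie-break
}

#' Simulate a node lesion and its functional-connectivity response
#'
#' The four-step in-silico lesion protocol: simulate the intact network,
#' delete the target node's row and column from the signed matrix, simulate
#' the lesioned network over a grid of the same length, and compare the
#' functional connectivity of the surviving nodes before and after. The
#' lesioned run starts from the intact initial condition restricted to the
#' survivors. Percent changes are reported relative to the pre-lesion
#' coefficient and are undefined (NA) where its magnitude is below
#' `pct_floor`, since ratios to near-zero baselines are meaningless; the
#' absolute difference matrix is always available.
#'
#' @param conn Intact [signed_connectivity()] matrix.
#' @param node Label of the node to remove.
#' @param x0 Intact initial condition (length N, in `[0, 1]`).
#' @param n_samples,dt Simulation grid (same length as the reference series).
#' @param opts [solver_options()].
#' @param pct_floor Magnitude floor on `fc_pre` below which percent change
#'   is reported as NA (default 0.05).
#' @return An object of class `lesion_report`: list with `removed_node`,
#'   `fc_pre`, `fc_post` (survivor correlation matrices), `delta`
#'   (`fc_post - fc_pre`), `percent_change`, `max_increase_pct`,
#'   `max_decrease_pct` (signed extrema of the off-diagonal percent
#'   changes; NA when fewer than 2 survivors or no defined entries), and
#'   the two simulated trajectories.
#' @export
lesion_response <- function(conn, node, x0, n_samples = 180L, dt = 3,
                            opts = solver_options(), pct_floor = 0.05) {
  labels <- node_labels(conn)
  if (length(x0) != length(labels)) {
    stop("x0 length must match network size", call. = FALSE)
  }
  if (is.numeric(node)) node <- labels[as.integer(node)]
  if (!(node %in% labels)) stop("unknown node label: ", node, call. = FALSE)
  survivors <- setdiff(labels, node)
  sim_pre <- simulate_egnb(conn, x0, n_samples = n_samples, dt = dt, opts = opts)
  conn_post <- lesion_node(conn, node)
  x0_post <- x0[match(survivors, labels)]
  sim_post <- simulate_egnb(conn_post, x0_post, n_samples = n_samples,
                            dt = dt, opts = opts)
  fc_pre <- functional_connectivity(subset_nodes(sim_pre, survivors))
  fc_post <- functional_connectivity(sim_post)
  delta <- fc_post - fc_pre
  percent <- 100 * delta / abs(fc_pre)
  percent[abs(fc_pre) < pct_floor] <- NA_real_
  diag(percent) <- NA_real_
  off <- percent[upper.tri(percent) | lower.tri(percent)]
  off <- off[!is.na(off)]
  structure(list(removed_node = node,
                 fc_pre = fc_pre, fc_post = fc_post,
                 delta = delta, percent_change = percent,
                 max_increase_pct = if (length(off) && any(off > 0)) max(off) else NA_real_,
                 max_decrease_pct = if (length(off) && any(off < 0)) min(off) else NA_real_,
                 pct_floor = pct_floor,
                 sim_pre = sim_pre, sim_post = sim_post),
            class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf("<lesion_report> removed '%s', %d survivors\n",
              x$removed_node, nrow(x$fc_post)))
  cat(sprintf("  max FC increase: %s%%   max FC decrease: %s%%  (floor |r| >= %g)\n",
              format(x$max_increase_pct, digits = 3),
              format(x$max_decrease_pct, digits = 3), x$pct_floor))
  invisible(x)
}
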