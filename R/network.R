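# Dynamic residue interaction networks: per-frame contact graphs at a
# C-beta (C-alpha for glycine) distance cutoff, per-residue betweenness
# centrality and average shortest path, and delta profiles between
# systems or against the first analysis frame.

#' Build the residue interaction network of one frame
#'
#' Nodes are residues; an edge joins two residues when the distance
#' between their C-beta atoms (C-alpha for glycine) is at most `cutoff`
#' (boundary inclusive).
#'
#' @param traj a [trajectory()] whose residues all provide CB (or CA for
#'   Gly).
#' @param frame frame index (default 1).
#' @param cutoff contact distance in Angstrom (default 6.7).
#' @return an [igraph::graph] with vertex attribute `resno`.
#' @export
build_rin <- function(traj, frame = 1, cutoff = 6.7) {
  sel <- select_atoms(traj, "CB_or_CA_for_GLY")
  x <- frame_coords(sel, frame)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$resno <- profile_resno(sel)
  g
}

# normalized betweenness of every node of one graph
rin_betweenness <- function(g) {
  n <- igraph::vcount(g)
  b <- igraph::betweenness(g, directed = FALSE, normalized = n > 2)
  list(value = unname(b), flag = rep(FALSE, n))
}

# average shortest path per node, unreachable pairs excluded and flagged
rin_avg_path <- function(g) {
  d <- igraph::distances(g)
  diag(d) <- NA
  reach <- is.finite(d)
  L <- rowSums(d * reach, na.rm = TRUE) / rowSums(reach, na.rm = TRUE)
  list(value = unname(L), flag = rowSums(!reach & !is.na(d)) > 0)
}

# mean of a per-node statistic over the frames of a window
.rin_profile <- function(traj, window, cutoff, node_stat, label) {
  if (length(window) < 1) stop("window must contain at least one frame")
  sel <- select_atoms(traj, "CB_or_CA_for_GLY")
  acc <- NULL
  flags <- NULL
  for (f in window) {
    st <- node_stat(build_rin(sel, f, cutoff))
    acc <- if (is.null(acc)) st$value else acc + st$value
    flags <- if (is.null(flags)) st$flag else flags | st$flag
  }
  prof <- residue_profile(acc / length(window), profile_resno(sel), label)
  attr(prof, "n_frames") <- length(window)
  attr(prof, "flagged") <- profile_resno(sel)[flags]
  prof
}

#' Mean betweenness-centrality profile over a trajectory window
#'
#' Per frame, each node's betweenness centrality -- the sum over
#' source-target pairs of the fraction of shortest paths passing through
#' the node -- is normalized by `(N-1)(N-2)/2` and then averaged over the
#' frames. Disconnected graphs are allowed; unreachable pairs contribute
#' nothing.
#'
#' @param traj a [trajectory()].
#' @param window integer frame indices (default all).
#' @param cutoff contact cutoff, Angstrom (default 6.7).
#' @return a `residue_profile` (unitless, in `[0, 1]`) with attribute
#'   `n_frames`.
#' @export
betweenness_profile <- function(traj, window = seq_len(n_frames(traj)),
                                cutoff = 6.7) {
  .rin_profile(traj, window, cutoff, rin_betweenness, "BC")
}

#' Mean average-shortest-path profile over a trajectory window
#'
#' Per frame, `L_i` is the mean hop distance from residue i to every
#' *reachable* residue (unreachable pairs are excluded from numerator and
#' denominator and the residue is flagged); profiles are averaged over
#' frames. A fully isolated residue has no defined L and is reported as
#' `NaN` for that frame.
#'
#' @inheritParams betweenness_profile
#' @return a `residue_profile` (hops) with attributes `n_frames` and
#'   `flagged` (residue numbers with unreachable pairs in some frame).
#' @export
shortest_path_profile <- function(traj, window = seq_len(n_frames(traj)),
                                  cutoff = 6.7) {
  .rin_profile(traj, window, cutoff, rin_avg_path, "L")
}

#' Difference between two residue profiles
#'
#' `delta_i = a_i - b_i` over the shared residues. The convention
#' (`"vs_first_frame"`: a system's windowed profile minus the profile of
#' the window's first frame alone; `"vs_other_system"`: wild minus
#' variant) is recorded as an attribute for auditability.
#'
#' @param profile_a,profile_b `residue_profile`s.
#' @param convention label recorded in the result's `convention`
#'   attribute.
#' @return a `residue_profile` on the residue intersection.
#' @export
delta_profile <- function(profile_a, profile_b,
                          convention = c("vs_first_frame",
                                         "vs_other_system")) {
  convention <- match.arg(convention)
  shared <- intersect(names(profile_a), names(profile_b))
  if (!length(shared))
    stop("comparison error: profiles share no residues")
  out <- residue_profile(as.numeric(profile_a[shared]) -
                         as.numeric(profile_b[shared]),
                         shared,
                         paste0("delta ", attr(profile_a, "label")))
  attr(out, "convention") <- convention
  out
}

#' Per-system delta profile against the first analysis frame
#'
#' Computes the windowed mean profile minus the single-graph profile of
#' the window's first frame -- the per-system delta convention used for
#' dynamic-network comparisons.
#'
#' @inheritParams betweenness_profile
#' @param statistic `"BC"` or `"L"`.
#' @return a `residue_profile` with `convention = "vs_first_frame"`.
#' @export
delta_vs_first_frame <- function(traj, statistic = c("BC", "L"),
                                 window = seq_len(n_frames(traj)),
                                 cutoff = 6.7) {
  statistic <- match.arg(statistic)
  fun <- if (statistic == "BC") betweenness_profile else shortest_path_profile
  delta_profile(fun(traj, window, cutoff),
                fun(traj, window[1], cutoff),
                "vs_first_frame")
}

#' Residue usage: wild-vs-variant difference of delta-BC profiles
#'
#' `usage_i = deltaBC_wild,i - deltaBC_variant,i`; positive values mark
#' residues whose role in shortest-path communication the variant has
#' reduced.
#'
#' @param delta_wild,delta_variant `residue_profile`s of delta-BC values.
#' @return a `residue_profile` on the shared residues.
#' @export
residue_usage <- function(delta_wild, delta_variant) {
  out <- delta_profile(delta_wild, delta_variant, "vs_other_system")
  attr(out, "label") <- "residue usage"
  out
}
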