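# Independent oracles and small fixture builders shared by the suite.
# The oracles deliberately use brute force / exhaustive enumeration and
# never call the code paths they check.

# ---- tiny trajectory builders ---------------------------------------------

# n one-atom (CA) residues at given coordinates; xyz_frames is a list of
# n x 3 matrices (or a single matrix for one frame). Glycine so the CA
# doubles as the network node under the CB-or-CA rule.
ca_traj <- function(xyz_frames, resname = "GLY") {
  if (is.matrix(xyz_frames)) xyz_frames <- list(xyz_frames)
  n <- nrow(xyz_frames[[1]])
  atoms <- data.frame(serial = seq_len(n), name = "CA", resname = resname,
                      chain = "A", resno = seq_len(n),
                      stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(xyz_frames, function(m) as.numeric(t(m))))
  trajectory(atoms, xyz)
}

# rigid rotation matrix about a given axis (degrees)
rot_about <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2)); th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

transform_frame <- function(traj, i, R = diag(3), t = c(0, 0, 0)) {
  set_frame_coords(traj, i, sweep(frame_coords(traj, i) %*% t(R), 2, t, "+"))
}

# ---- brute-force superposition oracle -------------------------------------

# Minimum RMSD over rotations by nested Euler-angle grid refinement;
# independent of the SVD route.
grid_rmsd_oracle <- function(mobile, reference, levels = 4) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rmsd_at <- function(a, b, c) {
    R <- rot_about(c(0, 0, 1), a) %*% rot_about(c(0, 1, 0), b) %*%
      rot_about(c(1, 0, 0), c)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  center <- c(0, 0, 0); width <- 180
  best <- Inf
  for (lev in seq_len(levels)) {
    gr <- seq(-width, width, length.out = 13)
    for (a in center[1] + gr) for (b in center[2] + gr / 2)
      for (c in center[3] + gr) {
        v <- rmsd_at(a, b, c)
        if (v < best) { best <- v; center <- c(a, b, c) }
      }
    width <- width / 5
  }
  best
}

# ---- exhaustive graph oracles ---------------------------------------------

# all simple paths between s and t in an adjacency matrix (small n only)
.all_paths <- function(adj, s, t) {
  n <- nrow(adj); out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { out[[length(out) + 1]] <<- path; return(invisible()) }
    for (w in which(adj[v, ])) if (!(w %in% path)) walk(c(path, w))
  }
  walk(s)
  out
}

# normalized betweenness by explicit path enumeration
enum_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- .all_paths(adj, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    geo <- paths[lens == min(lens)]
    for (v in setdiff(1:n, c(s, t))) {
      thru <- sum(vapply(geo, function(p) v %in% p, logical(1)))
      bc[v] <- bc[v] + thru / length(geo)
    }
  }
  if (n > 2) bc / ((n - 1) * (n - 2) / 2) else bc
}

# average shortest path per node by Floyd-Warshall, unreachable excluded
enum_avg_path <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[adj] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  vapply(1:n, function(i) {
    dd <- d[i, -i]; dd <- dd[is.finite(dd)]
    if (!length(dd)) NaN else mean(dd)
  }, numeric(1))
}

random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    adj[i, j] <- adj[j, i] <- runif(1) < p
  adj
}

# ---- misc -----------------------------------------------------------------

# mean silhouette width for a 1-D projection with known two-group labels
silhouette_1d <- function(x, lab) {
  d <- abs(outer(x, x, "-"))
  mean(vapply(seq_along(x), function(i) {
    own <- lab == lab[i]; own[i] <- FALSE
    a <- mean(d[i, own]); b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1)))
}

table1_path <- function() {
  system.file("extdata", "abca1_nsSNP_predictor_scores.csv",
              package = "vardyn")
}

# Two fully extended antiparallel strands (chains A and B) registered so
# the Kabsch-Sander bridge pattern forms: a beta-sheet fixture. The
# translation was fixed by a one-off grid search over registrations of
# the second (180-degree-rotated) strand.
make_antiparallel_sheet <- function(n = 6) {
  s1 <- vardyn:::build_chain(n, 180, 180)
  x1 <- frame_coords(s1, 1)
  x2 <- sweep(x1 %*% diag(c(-1, -1, 1)), 2, c(13.75, 6, 0), "+")
  atoms <- rbind(s1$atoms,
                 transform(s1$atoms, serial = serial + nrow(s1$atoms),
                           chain = "B"))
  trajectory(atoms, rbind(c(t(rbind(x1, x2)))))
}
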