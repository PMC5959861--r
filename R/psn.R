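#' Residue-type normalization values for interaction strengths
#'
#' Returns the per-residue-type normalization constants used in the
#' interaction-strength formula, read from the table shipped with the
#' package (standard values derived from a large protein dataset), with a
#' configurable default for residue types not in the table.
#'
#' @param path optional path to a two-column (\code{resname}, \code{norm})
#'   table; defaults to the packaged file.
#' @param default normalization for unknown residue types (default 100).
#' @return named numeric vector with attribute \code{default}.
#' @export
psn_normalization <- function(path = NULL, default = 100) {
  if (is.null(path))
    path <- system.file("extdata", "psn_normalization.tsv", package = "cntmd")
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  v <- stats::setNames(df$norm, df$resname)
  attr(v, "default") <- default
  v
}

norm_for <- function(resnames, norm_table) {
  v <- unname(norm_table[resnames])
  v[is.na(v)] <- attr(norm_table, "default") %||% 100
  if (any(v <= 0)) stop("PSN parameterization error: non-positive normalization")
  v
}

# side-chain heavy atoms per residue; glycine falls back to CA so it does
# not vanish from the network
side_chain_indices <- function(system, resid_set = NULL) {
  a <- system$atoms
  keep <- a$group == "receptor" & toupper(a$element) != "H" &
    !(a$name %in% c("N", "CA", "C", "O", "OXT"))
  # glycine: no side-chain heavy atoms -> use CA as pseudo-side-chain
  res <- residues(system)
  out <- list()
  for (r in seq_len(nrow(res))) {
    if (!is.null(resid_set) && !(res$resid[r] %in% resid_set)) next
    rng <- res$first[r]:res$last[r]
    sc <- rng[keep[rng]]
    if (length(sc) == 0) {
      ca <- rng[a$name[rng] == "CA"]
      sc <- ca
    }
    if (length(sc) > 0) out[[as.character(res$resid[r])]] <- sc
  }
  out
}

#' Per-frame residue interaction-strength matrix
#'
#' For side-chain heavy atoms of residues i and j, counts the distinct
#' inter-residue atom pairs within the distance cutoff (n_ij) and scales:
#' \deqn{I_{ij} = n_{ij} / \sqrt{N_i N_j} \times 100}
#' Sequence neighbours (|i - j| <= 1) are excluded as covalently coupled.
#'
#' @param coords full-system n x 3 coordinates (Angstrom).
#' @param system the \code{mol_system}.
#' @param distance_cutoff atom-pair cutoff in Angstrom (default 4.5).
#' @param norm_table normalization vector from
#'   \code{\link{psn_normalization}}.
#' @param resid_set optional residue subset (default: all receptor
#'   residues with side-chain or CA atoms).
#' @return symmetric matrix of interaction strengths with residue-index
#'   dimnames; zero diagonal.
#' @export
interaction_strength_frame <- function(coords, system, distance_cutoff = 4.5,
                                       norm_table = psn_normalization(),
                                       resid_set = NULL) {
  coords <- as.matrix(coords)
  sc <- side_chain_indices(system, resid_set)
  rid <- as.integer(names(sc))
  n <- length(sc)
  res <- residues(system)
  rn <- res$resname[match(rid, res$resid)]
  Nv <- norm_for(rn, norm_table)
  I <- matrix(0, n, n, dimnames = list(rid, rid))
  if (n < 2) return(I)
  c2 <- distance_cutoff^2
  # residue bounding centers for a cheap prefilter
  cen <- t(vapply(sc, function(ii) colMeans(coords[ii, , drop = FALSE]), numeric(3)))
  rad <- vapply(seq_len(n), function(r) {
    sqrt(max(rowSums(sweep(coords[sc[[r]], , drop = FALSE], 2, cen[r, ])^2)))
  }, numeric(1))
  for (i in seq_len(n - 1)) {
    ai <- coords[sc[[i]], , drop = FALSE]
    for (j in (i + 1):n) {
      if (abs(rid[i] - rid[j]) <= 1) next
      dc <- sqrt(sum((cen[i, ] - cen[j, ])^2))
      if (dc > rad[i] + rad[j] + distance_cutoff) next
      aj <- coords[sc[[j]], , drop = FALSE]
      d2 <- outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * ai %*% t(aj)
      nij <- sum(d2 <= c2 + 1e-12)
      if (nij > 0)
        I[i, j] <- I[j, i] <- nij / sqrt(Nv[i] * Nv[j]) * 100
    }
  }
  I
}

#' Per-frame interaction matrices over a trajectory window
#'
#' @param traj a \code{mol_trajectory}.
#' @param frames integer frame indices (default: all frames).
#' @param ... forwarded to \code{\link{interaction_strength_frame}}.
#' @return list of per-frame interaction-strength matrices.
#' @export
psn_frames <- function(traj, frames = NULL, ...) {
  stopifnot(inherits(traj, "mol_trajectory"))
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (length(frames) == 0) stop("psn_frames: empty frame window")
  lapply(frames, function(k)
    interaction_strength_frame(frame_coords(traj, k), traj$system, ...))
}

#' Build a protein structure network from per-frame interaction matrices
#'
#' Per frame, an edge exists between residues whose interaction strength
#' reaches \code{Imin}; the summary network keeps edges whose occupancy
#' (fraction of frames present) reaches \code{occupancy_min}, with the
#' mean strength over the frames where the edge is present.
#'
#' @param frame_mats list of per-frame interaction matrices (all with the
#'   same residue dimnames), from \code{\link{psn_frames}}.
#' @param Imin interaction-strength cutoff (default 3.0, the
#'   percent-like scale of the strength formula).
#' @param occupancy_min minimum edge occupancy in [0, 1] (default 0.5).
#' @return object of class \code{structure_network}: list with
#'   \code{nodes} (residue indices), \code{edges} (data.frame i, j,
#'   mean_strength, occupancy; i < j), and \code{parameters}.
#' @export
build_network <- function(frame_mats, Imin = 3.0, occupancy_min = 0.5) {
  if (length(frame_mats) == 0) stop("build_network: empty frame window")
  rid <- as.integer(rownames(frame_mats[[1]]))
  n <- length(rid)
  present <- matrix(0, n, n)
  ssum <- matrix(0, n, n)
  for (M in frame_mats) {
    hit <- M >= Imin
    present <- present + hit
    ssum <- ssum + ifelse(hit, M, 0)
  }
  nf <- length(frame_mats)
  occ <- present / nf
  ut <- upper.tri(occ)
  keep <- which(ut & occ >= occupancy_min, arr.ind = TRUE)
  edges <- data.frame(
    i = rid[keep[, 1]], j = rid[keep[, 2]],
    mean_strength = ssum[keep] / pmax(present[keep], 1),
    occupancy = occ[keep])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = rid, edges = edges,
                 parameters = list(Imin = Imin, occupancy_min = occupancy_min,
                                   n_frames = nf)),
            class = "structure_network")
}

#' @export
print.structure_network <- function(x, ...) {
  cat(sprintf("structure_network: %d nodes, %d edges (Imin = %g, occupancy >= %g over %d frames)\n",
              length(x$nodes), nrow(x$edges), x$parameters$Imin,
              x$parameters$occupancy_min, x$parameters$n_frames))
  invisible(x)
}

#' Write a structure network as an edge list
#' @param network a \code{structure_network}.
#' @param path output path (tab-delimited: i, j, mean_strength, occupancy).
#' @return \code{path}, invisibly.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Shortest allosteric communication pathways
#'
#' For every source-sink residue pair, finds the minimal-hop path through
#' network edges whose endpoint residues move in a correlated way
#' (|C(i,j)| >= corr_min on the edge). Among minimal-hop paths, ties are
#' broken by larger total (hence mean) edge strength, then by
#' lexicographic node order. Unreachable pairs yield a no-path record.
#'
#' @param network a \code{structure_network}.
#' @param dccm_mat correlation matrix with residue-index dimnames
#'   covering the network nodes (class \code{dccm_matrix} or plain).
#' @param sources,sinks integer residue-index vectors (network nodes).
#' @param corr_min correlation magnitude filter on edges (default 0.3).
#' @return object of class \code{pathway_list}: list of pathway records,
#'   each a list with \code{source}, \code{sink}, \code{nodes} (NULL when
#'   unreachable), \code{length} (hops; NA when unreachable), and
#'   \code{frequency} (NA until \code{\link{path_frequency}} fills it).
#' @export
shortest_paths <- function(network, dccm_mat, sources, sinks, corr_min = 0.3) {
  stopifnot(inherits(network, "structure_network"))
  nodes <- network$nodes
  if (!all(sources %in% nodes)) stop("shortest_paths: source not a network node")
  if (!all(sinks %in% nodes)) stop("shortest_paths: sink not a network node")
  lab <- as.character(nodes)
  n <- length(nodes)
  # adjacency restricted by the correlation filter
  W <- matrix(0, n, n, dimnames = list(lab, lab))
  E <- network$edges
  if (nrow(E) > 0) {
    ci <- as.character(E$i); cj <- as.character(E$j)
    ok <- rep(TRUE, nrow(E))
    if (!is.null(dccm_mat)) {
      cm <- abs(dccm_mat[cbind(match(ci, rownames(dccm_mat)),
                               match(cj, colnames(dccm_mat)))])
      ok <- !is.na(cm) & cm >= corr_min
    }
    ii <- match(ci, lab); jj <- match(cj, lab)
    W[cbind(ii[ok], jj[ok])] <- E$mean_strength[ok]
    W[cbind(jj[ok], ii[ok])] <- E$mean_strength[ok]
  }
  adj <- lapply(seq_len(n), function(v) which(W[v, ] > 0))

  out <- list()
  for (s in sources) {
    si <- match(s, nodes)
    dist <- rep(NA_integer_, n); dist[si] <- 0L
    # BFS level structure
    frontier <- si
    order_v <- si
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) for (u in adj[[v]])
        if (is.na(dist[u])) { dist[u] <- dist[v] + 1L; nxt <- c(nxt, u) }
      frontier <- sort(unique(nxt))
      order_v <- c(order_v, frontier)
    }
    # DP over the BFS DAG: maximize path strength sum, then lexicographic
    best_sum <- rep(-Inf, n); best_sum[si] <- 0
    best_path <- vector("list", n); best_path[[si]] <- si
    for (v in order_v) {
      if (v == si) next
      preds <- adj[[v]][!is.na(dist[adj[[v]]]) & dist[adj[[v]]] == dist[v] - 1L]
      for (p in preds) {
        if (is.null(best_path[[p]])) next
        cand_sum <- best_sum[p] + W[p, v]
        cand_path <- c(best_path[[p]], v)
        take <- FALSE
        if (cand_sum > best_sum[v] + 1e-12) take <- TRUE
        else if (abs(cand_sum - best_sum[v]) <= 1e-12 && !is.null(best_path[[v]]))
          take <- lex_less(nodes[cand_path], nodes[best_path[[v]]])
        else if (is.infinite(best_sum[v])) take <- TRUE
        if (take) { best_sum[v] <- cand_sum; best_path[[v]] <- cand_path }
      }
    }
    for (t in sinks) {
      ti <- match(t, nodes)
      if (s == t) {
        out[[length(out) + 1]] <- list(source = s, sink = t, nodes = s,
                                       length = 0L, frequency = NA_real_)
      } else if (is.na(dist[ti])) {
        out[[length(out) + 1]] <- list(source = s, sink = t, nodes = NULL,
                                       length = NA_integer_, frequency = NA_real_)
      } else {
        out[[length(out) + 1]] <- list(source = s, sink = t,
                                       nodes = nodes[best_path[[ti]]],
                                       length = dist[ti], frequency = NA_real_)
      }
    }
  }
  structure(out, class = "pathway_list")
}

lex_less <- function(a, b) {
  for (k in seq_len(min(length(a), length(b)))) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  length(a) < length(b)
}

#' Frequency of a pathway across frames
#'
#' Percentage of frames in which every consecutive residue pair of the
#' path is a per-frame network edge (interaction strength >= Imin).
#'
#' @param frame_mats per-frame interaction matrices
#'   (\code{\link{psn_frames}}).
#' @param path a pathway record (or plain integer node vector) with at
#'   least one edge.
#' @param Imin per-frame edge cutoff (default 3.0).
#' @return frequency in percent (0..100).
#' @export
path_frequency <- function(frame_mats, path, Imin = 3.0) {
  nodes <- if (is.list(path)) path$nodes else path
  if (is.null(nodes) || length(nodes) < 2)
    stop("path_frequency: path must have at least one edge")
  lab <- as.character(nodes)
  hit <- vapply(frame_mats, function(M) {
    i <- match(lab, rownames(M))
    if (anyNA(i)) return(FALSE)
    all(M[cbind(i[-length(i)], i[-1])] >= Imin)
  }, logical(1))
  100 * mean(hit)
}

#' Fill pathway frequencies in place
#' @param pathways a \code{pathway_list}.
#' @param frame_mats per-frame interaction matrices.
#' @param Imin per-frame edge cutoff.
#' @return the \code{pathway_list} with \code{frequency} set on every
#'   path that has at least one edge.
#' @export
score_path_frequencies <- function(pathways, frame_mats, Imin = 3.0) {
  for (k in seq_along(pathways)) {
    p <- pathways[[k]]
    if (!is.null(p$nodes) && length(p$nodes) >= 2)
      pathways[[k]]$frequency <- path_frequency(frame_mats, p, Imin)
  }
  pathways
}

#' Most frequent starting and ending nodes over a pathway set
#'
#' Counts source and sink occurrences weighted by path frequency
#' (frequency/100; paths without a frequency weigh 1), ordered by count
#' descending, then residue index ascending.
#'
#' @param pathways a \code{pathway_list} (paths without nodes are skipped).
#' @param k how many top nodes per side (default 3).
#' @return list with data.frames \code{top_sources} and \code{top_sinks}
#'   (columns \code{resid}, \code{count}).
#' @export
node_frequency_summary <- function(pathways, k = 3L) {
  ok <- Filter(function(p) !is.null(p$nodes), pathways)
  if (length(ok) == 0) stop("node_frequency_summary: empty pathway list")
  w <- vapply(ok, function(p) if (is.na(p$frequency)) 1 else p$frequency / 100,
              numeric(1))
  tally <- function(ids) {
    agg <- tapply(w, ids, sum)
    df <- data.frame(resid = as.integer(names(agg)), count = as.numeric(agg))
    df <- df[order(-df$count, df$resid), , drop = FALSE]
    rownames(df) <- NULL
    utils::head(df, k)
  }
  list(top_sources = tally(vapply(ok, function(p) p$source, numeric(1))),
       top_sinks = tally(vapply(ok, function(p) p$sink, numeric(1))))
}

#' Write pathways as a text table
#' @param pathways a \code{pathway_list}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pathways <- function(pathways, path) {
  rows <- lapply(pathways, function(p) data.frame(
    source = p$source, sink = p$sink,
    nodes = if (is.null(p$nodes)) "no-path" else paste(p$nodes, collapse = "-"),
    length = p$length, frequency = p$frequency))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
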