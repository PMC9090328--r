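#' Region-grown overall area of activation
#'
#' Breadth-first closure from the peak node over edge-adjacent nodes that
#' are significant in the activation map: the "overall area of activation".
#' If the seed itself is not significant, growth starts from the nearest
#' significant node (with a warning). An empty significance mask yields an
#' empty area (with a warning).
#'
#' @param map an \code{activation_map}
#' @param mesh the \code{cortical_mesh} the map lives on
#' @param adjacency \code{"edge"} (default) or \code{"face"}
#' @return object of class \code{activation_area}: \code{nodes} (integer
#'   set), \code{area_mm2}, \code{seed}
#' @export
grow_area <- function(map, mesh, adjacency = c("edge", "face")) {
  adjacency <- match.arg(adjacency)
  adj <- if (adjacency == "edge") mesh$adjacency else mesh$face_adjacency
  mask <- map$mask
  seed <- map$peak_node
  if (!any(mask)) {
    warning("empty significance mask; empty activation area")
    return(structure(list(nodes = integer(0), area_mm2 = 0, seed = seed),
                     class = "activation_area"))
  }
  if (!mask[seed]) {
    cand <- which(mask)
    d2 <- rowSums(sweep(mesh$nodes[cand, , drop = FALSE], 2,
                        mesh$nodes[seed, ])^2)
    seed <- cand[which.min(d2)]
    warning("peak node not significant; growing from nearest significant node ",
            seed)
  }
  visited <- logical(length(mask))
  visited[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    nb <- unique(unlist(adj[frontier], use.names = FALSE))
    nb <- nb[mask[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  nodes <- which(visited)
  structure(list(nodes = nodes, area_mm2 = sum(mesh$node_area[nodes]),
                 seed = seed),
            class = "activation_area")
}

#' FWHM area of the peak
#'
#' The connected subset of the activation area, containing the seed, where
#' the magnitude of the mean change is at least half the peak change (nodes
#' exactly at half maximum are included). Area is the sum of member node
#' areas (mm^2).
#'
#' @param map an \code{activation_map}
#' @param area an \code{\link{grow_area}} result
#' @param mesh the mesh
#' @return object of class \code{activation_area}
#' @export
fwhm_area <- function(map, area, mesh) {
  if (!length(area$nodes))
    return(structure(list(nodes = integer(0), area_mm2 = 0, seed = area$seed),
                     class = "activation_area"))
  seed <- area$seed
  peak_val <- abs(map$mean_change[seed])
  ok <- logical(length(map$mean_change))
  ok[area$nodes] <- abs(map$mean_change[area$nodes]) >= 0.5 * peak_val
  visited <- logical(length(ok))
  if (ok[seed]) {
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nb <- unique(unlist(mesh$adjacency[frontier], use.names = FALSE))
      nb <- nb[ok[nb] & !visited[nb]]
      visited[nb] <- TRUE
      frontier <- nb
    }
  }
  nodes <- which(visited)
  structure(list(nodes = nodes, area_mm2 = sum(mesh$node_area[nodes]),
                 seed = seed),
            class = "activation_area")
}

#' Topographic summary metrics of an activation map
#'
#' Peak amplitude (group-mean change at the seed node over the peak
#' window), peak latency, peak location (mm), FWHM area and overall area.
#'
#' @param map an \code{activation_map}
#' @param mesh the mesh
#' @param area optional precomputed \code{\link{grow_area}} result
#' @return list of class \code{topo_metrics}: \code{peak_uM},
#'   \code{latency_s}, \code{location_mm}, \code{fwhm_mm2},
#'   \code{overall_mm2}, \code{peak_node}
#' @export
peak_metrics <- function(map, mesh, area = NULL) {
  if (is.null(area)) area <- suppressWarnings(grow_area(map, mesh))
  fw <- fwhm_area(map, area, mesh)
  seed <- if (length(area$nodes)) area$seed else map$peak_node
  structure(list(peak_uM = map$mean_change[seed],
                 latency_s = map$latency_s,
                 location_mm = mesh$nodes[seed, ],
                 fwhm_mm2 = fw$area_mm2,
                 overall_mm2 = area$area_mm2,
                 peak_node = map$peak_node, seed = seed),
            class = "topo_metrics")
}

#' Euclidean distance between two activation peaks (mm)
#' @param a,b \code{topo_metrics} in the same coordinate frame
#' @export
peak_distance <- function(a, b) {
  sqrt(sum((a$location_mm - b$location_mm)^2))
}

#' Partition two activation areas into exclusive and overlap regions
#'
#' @param area_a,area_b \code{activation_area} objects on the same mesh
#' @param mesh the mesh
#' @return list of class \code{overlap_partition}: node sets and areas
#'   (mm^2) for \code{only_a}, \code{only_b}, \code{overlap}
#' @export
partition_overlap <- function(area_a, area_b, mesh) {
  n <- length(mesh$node_area)
  if (length(area_a$nodes) && max(area_a$nodes) > n ||
      length(area_b$nodes) && max(area_b$nodes) > n)
    stop("activation areas reference nodes outside the mesh")
  ov <- intersect(area_a$nodes, area_b$nodes)
  oa <- setdiff(area_a$nodes, ov)
  ob <- setdiff(area_b$nodes, ov)
  structure(list(only_a = oa, only_b = ob, overlap = ov,
                 only_a_mm2 = sum(mesh$node_area[oa]),
                 only_b_mm2 = sum(mesh$node_area[ob]),
                 overlap_mm2 = sum(mesh$node_area[ov])),
            class = "overlap_partition")
}

#' Node-wise between-condition contrast within activation regions
#'
#' At every node of the union of the two areas, compares the two groups'
#' per-subject peak-window mean changes with a two-sample Student's t-test
#' (pooled variance, no multiple-comparison correction by default), and
#' reports the fraction of significantly different nodes in each region of
#' the overlap partition.
#'
#' @param images_a,images_b per-subject \code{nirs_image} lists for the two
#'   (independent) groups
#' @param map_a,map_b the groups' \code{activation_map}s (define the peak
#'   windows and baselines)
#' @param partition an \code{\link{partition_overlap}} result
#' @param chromophore \code{"hbo"} or \code{"hb"}
#' @param alpha per-node significance level
#' @param bonferroni divide alpha by the number of tested nodes
#' @return list: \code{fraction} (named: only_a, only_b, overlap),
#'   \code{t}, \code{p}, \code{significant} (per union node, named by node
#'   index)
#' @export
nodewise_contrast <- function(images_a, images_b, map_a, map_b, partition,
                              chromophore = c("hbo", "hb"), alpha = 0.05,
                              bonferroni = FALSE) {
  chromophore <- match.arg(chromophore)
  if (length(images_a) < 2 || length(images_b) < 2)
    stop("each group needs at least 2 subjects")
  union_nodes <- sort(unique(c(partition$only_a, partition$only_b,
                               partition$overlap)))
  subj_change <- function(images, map) {
    vapply(images, function(im) {
      m <- im[[chromophore]]
      rowMeans(m[union_nodes, map$window_idx, drop = FALSE]) -
        rowMeans(m[union_nodes, map$baseline_idx, drop = FALSE])
    }, numeric(length(union_nodes)))
  }
  A <- subj_change(images_a, map_a)        # nodes x S_a
  B <- subj_change(images_b, map_b)
  na <- ncol(A); nb <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (na - 1)
  v2 <- rowSums((B - m2)^2) / (nb - 1)
  sp2 <- ((na - 1) * v1 + (nb - 1) * v2) / (na + nb - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tstat), na + nb - 2)
  thr <- if (bonferroni) alpha / length(union_nodes) else alpha
  sig <- p <= thr
  sig[!is.finite(p)] <- FALSE
  frac <- function(nodes) {
    if (!length(nodes)) return(NA_real_)
    mean(sig[match(nodes, union_nodes)])
  }
  list(fraction = c(only_a = frac(partition$only_a),
                    only_b = frac(partition$only_b),
                    overlap = frac(partition$overlap)),
       t = stats::setNames(tstat, union_nodes),
       p = stats::setNames(p, union_nodes),
       significant = stats::setNames(sig, union_nodes))
}
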