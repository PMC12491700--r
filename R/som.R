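## Supra-hexagonal self-organising map: a lattice of concentric hexagon
## rings trained by sequential SOM updates with a Gaussian neighbourhood
## kernel, partitioned into lattice-connected clusters by region growing on
## U-matrix minima.

## axial hex neighbour directions (pointy-top)
.hex_dirs <- rbind(c(1, 0), c(1, -1), c(0, -1), c(-1, 0), c(-1, 1), c(0, 1))

.axial_to_xy <- function(qr) {
    cbind(x = qr[, 1] + qr[, 2] / 2, y = qr[, 2] * sqrt(3) / 2)
}

#' Build an untrained supra-hexagonal lattice
#'
#' Concentric hexagon rings: \code{r} rings give \eqn{3r^2 - 3r + 1} nodes
#' (r = 1 is a single centre node, r = 5 gives the 61-hexagon map).  Nodes
#' are ordered deterministically centre-outward, ring by ring.
#'
#' @param r number of rings (>= 1).
#' @param M codebook dimension (columns of the training matrix).
#' @return an untrained \linkS4class{SupraHexMap}.
#' @examples
#' buildLattice(5)   # 61 nodes
#' @export
buildLattice <- function(r, M = 2L) {
    r <- as.integer(r)
    if (is.na(r) || r < 1) stop("r must be an integer >= 1")
    axial <- matrix(c(0, 0), ncol = 2)
    ring_idx <- 1L
    for (k in seq_len(r - 1L)) {
        pos <- k * .hex_dirs[5, ]      # start of ring k, walk the 6 sides
        ring_k <- matrix(NA_real_, nrow = 6 * k, ncol = 2)
        step <- 1L
        for (side in 1:6) {
            for (j in seq_len(k)) {
                ring_k[step, ] <- pos
                pos <- pos + .hex_dirs[side, ]
                step <- step + 1L
            }
        }
        axial <- rbind(axial, ring_k)
        ring_idx <- c(ring_idx, rep(k + 1L, 6 * k))
    }
    coords <- .axial_to_xy(axial)
    rownames(coords) <- sprintf("H%d", seq_len(nrow(coords)))
    dd <- as.matrix(dist(coords))
    neighbours <- lapply(seq_len(nrow(coords)), function(i)
        which(dd[i, ] > 0 & dd[i, ] < 1.01))
    new("SupraHexMap", rings = r, coords = coords,
        ring = as.integer(ring_idx), neighbours = neighbours,
        codebook = matrix(NA_real_, nrow(coords), M),
        trained = FALSE, qe = c(NA_real_, NA_real_))
}

.init_codebook <- function(map, data) {
    ## linear initialisation along the first two principal directions
    N <- nrow(map@coords)
    M <- ncol(data)
    centre <- colMeans(data)
    cb <- matrix(rep(centre, each = N), nrow = N)
    u <- scale(map@coords, scale = FALSE)
    span <- apply(abs(u), 2, max)
    span[span == 0] <- 1
    u <- sweep(u, 2, span, "/")    # in [-1, 1] per axis
    if (nrow(data) >= 2) {
        pc <- prcomp(data, center = TRUE, scale. = FALSE)
        n_dir <- min(2L, ncol(pc$rotation), M)
        for (d in seq_len(n_dir)) {
            if (pc$sdev[d] > 0)
                cb <- cb + outer(u[, d], pc$rotation[, d] * pc$sdev[d] * 2)
        }
    }
    cb
}

.quantization_error <- function(cb, data) {
    mean(vapply(seq_len(nrow(data)), function(i) {
        d2 <- rowSums((cb - matrix(data[i, ], nrow(cb), ncol(cb),
                                   byrow = TRUE))^2)
        sqrt(min(d2))
    }, numeric(1)))
}

#' Default two-phase training schedule
#'
#' The schedule is matched to the deterministic linear (principal-plane)
#' initialisation, which already places codebooks close to the data: an
#' organising phase with a gentle learning rate (0.02 to 0.005) and a
#' neighbourhood width shrinking from about half the map radius to 0.4
#' orders the map without destroying the initialisation, then a convergence
#' phase (sigma 0.3 to 0.05) degenerates into winner-only updates -- an
#' online k-means refinement that settles each codebook on its local data
#' mean and drives the quantization error below its initial value.  Input
#' order is reshuffled every pass under \code{rng_seed}.
#'
#' @param map a \linkS4class{SupraHexMap} (sets the update counts and the
#'   initial sigma).
#' @param rng_seed integer seed for input-order shuffling.
#' @return list of phase definitions plus the seed.
#' @export
somSchedule <- function(map, rng_seed = 1L) {
    N <- nrow(map@coords)
    sigma0 <- max(1.2, (map@rings - 1) / 2)
    list(phases = list(
             list(steps = 10L * N, alpha = c(0.02, 0.005),
                  sigma = c(sigma0, 0.4)),
             list(steps = 20L * N, alpha = c(0.05, 0.01),
                  sigma = c(0.3, 0.05))),
         rng_seed = as.integer(rng_seed))
}

#' Train a supra-hexagonal map by sequential SOM updates
#'
#' Per step the best-matching unit w minimises the Euclidean codebook
#' distance to the input vector, then every node i moves towards the input:
#' \deqn{m_i(t+1) = m_i(t) + \alpha(t)\, h_{wi}(t)\, [x(t) - m_i(t)]}
#' with the Gaussian kernel
#' \eqn{h_{wi}(t) = \exp(-\|r_w - r_i\|^2 / 2\sigma(t)^2)} on the lattice
#' location vectors.  Codebooks are linearly initialised along the first two
#' principal directions of the data (deterministic), and the mean
#' quantization error is recorded before and after training.
#'
#' @param map untrained \linkS4class{SupraHexMap}.
#' @param data numeric gene x M matrix with row names.
#' @param schedule from \code{\link{somSchedule}}.
#' @return the trained map.
#' @export
trainSom <- function(map, data, schedule = somSchedule(map)) {
    data <- as.matrix(data)
    if (nrow(data) == 0) stop("empty training data")
    if (any(!is.finite(data))) stop("training data must be finite")
    if (ncol(data) != ncol(map@codebook))
        map@codebook <- matrix(NA_real_, nrow(map@coords), ncol(data))
    cb <- .init_codebook(map, data)
    qe0 <- .quantization_error(cb, data)
    coords <- map@coords
    set.seed(schedule$rng_seed)
    for (phase in schedule$phases) {
        Tn <- phase$steps
        order_pool <- integer(0)
        for (t in seq_len(Tn)) {
            if (length(order_pool) == 0)
                order_pool <- sample(nrow(data))
            i <- order_pool[1]
            order_pool <- order_pool[-1]
            x <- data[i, ]
            frac <- if (Tn > 1) (t - 1) / (Tn - 1) else 0
            alpha <- phase$alpha[1] + frac * diff(phase$alpha)
            sigma <- phase$sigma[1] + frac * diff(phase$sigma)
            d2 <- rowSums((cb - matrix(x, nrow(cb), ncol(cb),
                                       byrow = TRUE))^2)
            w <- which.min(d2)           # ties: lowest node index
            ld2 <- rowSums((coords - matrix(coords[w, ], nrow(coords), 2,
                                            byrow = TRUE))^2)
            h <- exp(-ld2 / (2 * sigma^2))
            cb <- cb + alpha * h * (matrix(x, nrow(cb), ncol(cb),
                                           byrow = TRUE) - cb)
        }
    }
    map@codebook <- cb
    map@trained <- TRUE
    map@qe <- c(qe0, .quantization_error(cb, data))
    map
}

#' Assign genes to their best-matching map node
#'
#' @param map trained \linkS4class{SupraHexMap}.
#' @param data gene x M matrix (same M as the codebooks).
#' @return named integer vector of node indices; ties go to the lowest
#'   node index.
#' @export
mapGenes <- function(map, data) {
    if (!map@trained) stop("map is not trained")
    data <- as.matrix(data)
    if (ncol(data) != ncol(map@codebook))
        stop("dimension mismatch: data has ", ncol(data),
             " columns, codebook ", ncol(map@codebook))
    cb <- map@codebook
    setNames(vapply(seq_len(nrow(data)), function(i) {
        d2 <- rowSums((cb - matrix(data[i, ], nrow(cb), ncol(cb),
                                   byrow = TRUE))^2)
        which.min(d2)
    }, integer(1)), rownames(data))
}

#' Partition a trained map into lattice-connected clusters
#'
#' Topology-preserving clustering: seeds are the local minima of the
#' U-matrix (mean codebook distance to lattice neighbours); regions grow by
#' repeatedly attaching the unassigned node whose codebook is closest to an
#' adjacent region's mean; lattice-adjacent region pairs with the most
#' similar means are then merged until \code{k} regions remain.  Every
#' cluster is connected on the lattice by construction.
#'
#' @param map trained \linkS4class{SupraHexMap}.
#' @param k number of clusters (1..N; at most the number of U-matrix
#'   minima).
#' @return list: \code{cluster} (named integer per node, labels 1..k),
#'   \code{labels} ("C1".."Ck"), \code{u} (U-matrix values).
#' @export
partitionMap <- function(map, k) {
    if (!map@trained) stop("map is not trained")
    N <- nrow(map@coords)
    if (k < 1 || k > N) stop("k must be in 1..N")
    cb <- map@codebook
    u <- vapply(seq_len(N), function(i) {
        nb <- map@neighbours[[i]]
        mean(sqrt(rowSums((cb[nb, , drop = FALSE] -
            matrix(cb[i, ], length(nb), ncol(cb), byrow = TRUE))^2)))
    }, numeric(1))
    seeds <- which(vapply(seq_len(N), function(i)
        all(u[i] <= u[map@neighbours[[i]]]), logical(1)))
    ## adjacent tied minima would seed duplicate regions; keep one per
    ## lattice-connected plateau
    keep <- rep(TRUE, length(seeds))
    for (a in seq_along(seeds)) {
        if (!keep[a]) next
        for (b in seq_along(seeds)) {
            if (b <= a || !keep[b]) next
            if (seeds[b] %in% map@neighbours[[seeds[a]]] &&
                abs(u[seeds[a]] - u[seeds[b]]) < 1e-12)
                keep[b] <- FALSE
        }
    }
    seeds <- seeds[keep]
    if (k > length(seeds))
        stop("k exceeds the number of U-matrix minima (", length(seeds), ")")
    cluster <- integer(N)
    cluster[seeds] <- seq_along(seeds)
    sums <- cb[seeds, , drop = FALSE]
    cnts <- rep(1L, length(seeds))
    while (any(cluster == 0)) {
        best <- NULL; best_d <- Inf
        for (i in which(cluster == 0)) {
            regs <- unique(cluster[map@neighbours[[i]]])
            regs <- regs[regs > 0]
            for (rg in regs) {
                d <- sqrt(sum((cb[i, ] - sums[rg, ] / cnts[rg])^2))
                if (d < best_d) { best_d <- d; best <- c(i, rg) }
            }
        }
        if (is.null(best)) stop("lattice not connected")   # cannot happen
        cluster[best[1]] <- best[2]
        sums[best[2], ] <- sums[best[2], ] + cb[best[1], ]
        cnts[best[2]] <- cnts[best[2]] + 1L
    }
    ## merge closest lattice-adjacent regions down to k
    while (length(unique(cluster)) > k) {
        regs <- sort(unique(cluster))
        means <- t(vapply(regs, function(rg)
            colMeans(cb[cluster == rg, , drop = FALSE]), numeric(ncol(cb))))
        adj <- function(r1, r2) {
            any(vapply(which(cluster == r1), function(i)
                any(cluster[map@neighbours[[i]]] == r2), logical(1)))
        }
        best <- NULL; best_d <- Inf
        for (a in seq_along(regs)) for (b in seq_along(regs)) {
            if (b <= a) next
            if (!adj(regs[a], regs[b])) next
            d <- sqrt(sum((means[a, ] - means[b, ])^2))
            if (d < best_d) { best_d <- d; best <- c(regs[a], regs[b]) }
        }
        cluster[cluster == best[2]] <- best[1]
    }
    relabel <- match(cluster, sort(unique(cluster)))
    list(cluster = setNames(relabel, rownames(map@coords)),
         labels = sprintf("C%d", seq_len(max(relabel))), u = u)
}

#' Gene lists per map cluster
#'
#' @param partition from \code{\link{partitionMap}}.
#' @param assignment gene-to-node assignment from \code{\link{mapGenes}}.
#' @return named list of gene id vectors, one per cluster.
#' @export
clusterGenes <- function(partition, assignment) {
    cl <- partition$cluster[assignment]
    split(names(assignment), factor(cl, levels = seq_along(partition$labels),
                                    labels = partition$labels))
}
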