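suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

# brute-force sphere offset enumeration (independent oracle)
bruteSphere <- function(r) {
    n <- 0L
    rr <- ceiling(r)
    for (dx in -rr:rr) for (dy in -rr:rr) for (dz in -rr:rr)
        if (dx^2 + dy^2 + dz^2 <= r^2) n <- n + 1L
    n
}

# small all-true grid
cubeGrid <- function(d) volumeGrid(c(d, d, d))

# ellipsoid-mask desk grid
deskGrid <- function(d = 12) {
    volumeGrid(c(d, d, d), mask = ellipsoidMask(c(d, d, d)))
}

# cohort where every subject carries the same fixed per-condition
# templates in a block ROI
templateCohort <- function(nSubjects, grid, lo, hi, templates = NULL,
                           noiseSD = 1, signalScale = 1, seed = 1,
                           smoothFWHM = 2, ...) {
    vox <- roiBlock(grid, lo, hi)
    roi <- list(voxels = vox)
    if (!is.null(templates)) roi$templates <- templates
    cfg <- syntheticConfig(
        nSubjects = nSubjects, grid = grid,
        rois = list(roi), noiseSD = noiseSD, signalScale = signalScale,
        smoothFWHM = smoothFWHM, seed = seed, ...)
    c(generateCohort(cfg), list(voxels = vox, config = cfg))
}

# slow reference TFCE: literal Riemann sum using an R flood fill
referenceTFCE <- function(vol, E, H, dh, connectivity = 26) {
    dm <- dim(vol)
    out <- array(0, dm)
    mx <- max(vol)
    if (mx <= 0) return(out)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    m <- rowSums(abs(offs))
    offs <- offs[m > 0 & m <= c("6" = 1, "18" = 2, "26" = 3)[
        as.character(connectivity)], , drop = FALSE]
    hseq <- seq(dh, mx, by = dh)
    for (h in hseq) {
        fg <- vol >= h
        lab <- array(0L, dm)
        nxt <- 0L
        for (s in which(fg)) {
            if (lab[s] != 0L) next
            nxt <- nxt + 1L
            queue <- s
            lab[s] <- nxt
            while (length(queue)) {
                v <- queue[[1]]
                queue <- queue[-1]
                cc <- arrayInd(v, dm)
                nb <- sweep(offs, 2, as.integer(cc), "+")
                ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
                    nb[, 2] >= 1 & nb[, 2] <= dm[2] &
                    nb[, 3] >= 1 & nb[, 3] <= dm[3]
                nb <- nb[ok, , drop = FALSE]
                lin <- nb[, 1] + dm[1] * (nb[, 2] - 1L) +
                    dm[1] * dm[2] * (nb[, 3] - 1L)
                new <- lin[fg[lin] & lab[lin] == 0L]
                lab[new] <- nxt
                queue <- c(queue, new)
            }
        }
        sizes <- tabulate(lab[fg])
        out[fg] <- out[fg] + sizes[lab[fg]]^E * h^H * dh
    }
    out
}

# exact binomial upper tail by direct summation (oracle)
bruteUpperTail <- function(k, n, p) {
    if (k <= 0) return(1)
    if (k > n) return(0)
    sum(dbinom(k:n, n, p))
}
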