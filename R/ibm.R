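#' Parameters of the individual-based model
#'
#' The individual-based model (IBM) simulates a fixed-size community of `N`
#' cells under discrete-generation Wright-Fisher reproduction, resource
#' competition in `n` niches, horizontal transfer of a focal beneficial
#' allele and immigration of unique non-carrier genotypes. Each cell is a
#' triple (focal-locus allele, background genotype, niche): the focal locus
#' is transferable (allele 1 = adapted), the background genotype is not,
#' and the niche indexes the resource the cell is best adapted to.
#'
#' @param N Community size (cells), constant over the run.
#' @param n Number of resource niches (>= 1).
#' @param z Association of a cell with its assigned niche, in `[0, 1]`:
#'   `z = 1` means a cell competes only in its own niche, `z = 1/n` equal
#'   competition in all niches. Values below `1/n` (preferring foreign
#'   niches) are allowed with a warning.
#' @param s Selection coefficient: carriers have fitness `1 + s`.
#' @param r Transfer-rate coefficient; a non-carrier acquires the allele
#'   with probability `C * r` per generation, `C` the carrier fraction.
#' @param m Migration rate: each cell is replaced by an immigrant with
#'   probability `m` per generation; immigrants are unique non-carriers.
#' @param C0 Initial carrier fraction; `round(C0 * N)` founding carriers
#'   form a single clone.
#' @param t_end Number of generations to simulate.
#' @param seed RNG seed used by [ibm_run()].
#' @return An object of class `"ibm_params"`.
#' @export
ibm_params <- function(N, n = 1, z = 1, s, r, m, C0, t_end, seed = 1L) {
  stopifnot(N >= 1, n >= 1, n == round(n), z >= 0, z <= 1,
            s >= -1, r >= 0, r <= 1, m >= 0, m <= 1,
            C0 >= 0, C0 <= 1, t_end >= 0)
  if (n > 1 && z < 1 / n)
    warning(sprintf("z = %g < 1/n = %g: cells prefer foreign niches", z, 1 / n))
  structure(list(N = as.integer(N), n = as.integer(n), z = z, s = s, r = r,
                 m = m, C0 = C0, t_end = as.integer(t_end),
                 seed = as.integer(seed)),
            class = "ibm_params")
}

.new_community <- function(focal, background, niche, count, N, n, next_id) {
  structure(
    data.frame(focal = as.numeric(focal), background = as.numeric(background),
               niche = as.integer(niche), count = as.integer(count)),
    N = as.integer(N), n = as.integer(n), next_id = as.numeric(next_id),
    class = c("ibm_community", "data.frame")
  )
}

#' Initialise an IBM community
#'
#' Creates the founding community: `round(C0 * N)` carriers forming one
#' clone (focal allele 1, background genotype 1) and `N - round(C0 * N)`
#' non-carriers that are each a unique genotype (focal allele equal to the
#' background identifier, both > 1). Niches are assigned uniformly at
#' random to every cell. Cells with identical (focal, background, niche)
#' are stored as one row with a count, so large communities stay compact.
#'
#' @param p An [ibm_params()] object.
#' @return An `"ibm_community"` data frame with columns `focal`,
#'   `background`, `niche`, `count` and attributes `N`, `n`, `next_id`.
#' @export
init_community <- function(p) {
  stopifnot(inherits(p, "ibm_params"))
  k <- round(p$C0 * p$N)
  if (k == 0 && p$C0 > 0)
    warning("C0 * N rounds to 0 carriers; the sweep cannot start")
  nn <- p$N - k
  car <- if (k > 0) {
    niche_c <- tabulate(sample.int(p$n, k, replace = TRUE), p$n)
    keep <- niche_c > 0
    data.frame(focal = 1, background = 1, niche = which(keep),
               count = niche_c[keep])
  }
  non <- if (nn > 0) {
    ids <- seq.int(2, length.out = nn)
    data.frame(focal = ids, background = ids,
               niche = sample.int(p$n, nn, replace = TRUE), count = 1L)
  }
  st <- rbind(car, non)
  .new_community(st$focal, st$background, st$niche, st$count,
                 p$N, p$n, next_id = nn + 2)
}

#' Niche-association weights
#'
#' The niche-association matrix `sigma`: row `i` gives the association of a
#' cell assigned to niche `i` with each niche `j`, `z` for its own niche
#' and `(1 - z)/(n - 1)` for every other (1 for the single niche when
#' `n = 1`, regardless of `z`). Rows sum to 1.
#'
#' @param p An [ibm_params()] object.
#' @return An `n x n` matrix of niche associations.
#' @export
niche_weights <- function(p) {
  n <- p$n
  if (n == 1) return(matrix(1, 1, 1))
  sigma <- matrix((1 - p$z) / (n - 1), n, n)
  diag(sigma) <- p$z
  sigma
}

#' Resource allocation across niches
#'
#' Each of the `n` niches holds a resource share `N / n` per generation. A
#' cell of class `i` has competitive weight `omega_ij = f_i * sigma_ij` in
#' niche `j` (`f_i = 1 + s` for carriers, 1 otherwise) and obtains
#' `R_ij = (omega_ij / Omega_j) * (N / n)` from it, where `Omega_j` is the
#' summed competitive weight of all cells in niche `j`. Niches without any
#' competitive weight distribute nothing (their share is forfeited). The
#' total `R_i = sum_j R_ij` is the mean offspring number of a class-`i`
#' cell used by [reproduce()].
#'
#' @param state An `"ibm_community"`.
#' @param p An [ibm_params()] object.
#' @return A list with per-class vectors `f` and `R`, the per-class-by-niche
#'   matrix `R_ij`, the per-niche summed weights `Omega` and the
#'   association matrix `sigma`.
#' @export
allocate_resources <- function(state, p) {
  if (nrow(state) == 0 || sum(state$count) == 0)
    stop("community is empty")
  N <- attr(state, "N"); n <- p$n
  sigma <- niche_weights(p)
  f <- ifelse(state$focal == 1, 1 + p$s, 1)
  w <- state$count * f
  W <- vapply(seq_len(n), function(j) sum(w[state$niche == j]), numeric(1))
  Omega <- as.vector(t(sigma) %*% W) # summed competitive weight per niche
  share <- ifelse(Omega > 0, (N / n) / Omega, 0)
  R_ij <- (f * sigma[state$niche, , drop = FALSE]) *
    rep(share, each = nrow(state))
  R <- rowSums(R_ij)
  list(f = f, R = R, R_ij = R_ij, Omega = Omega, sigma = sigma)
}

#' Wright-Fisher reproduction
#'
#' Draws the next generation of exactly `N` cells. Cells of class `i` have
#' mean offspring `R_i`; independent Poisson offspring conditioned on a
#' fixed total `N` give multinomial class counts with probabilities
#' proportional to `count_i * R_i`, which is what is sampled. Offspring
#' inherit all three class labels.
#'
#' @param state An `"ibm_community"`.
#' @param resources Result of [allocate_resources()] for `state`.
#' @param p An [ibm_params()] object.
#' @return The community after reproduction.
#' @export
reproduce <- function(state, resources, p) {
  w <- state$count * resources$R
  if (all(w <= 0)) stop("all classes received zero resources")
  cnt <- as.integer(stats::rmultinom(1, attr(state, "N"), w))
  keep <- cnt > 0
  .new_community(state$focal[keep], state$background[keep],
                 state$niche[keep], cnt[keep],
                 attr(state, "N"), attr(state, "n"), attr(state, "next_id"))
}

#' Horizontal transfer step
#'
#' Every non-carrier independently acquires the focal allele with
#' probability `C * r`, where `C` is the current carrier fraction.
#' Converted cells keep their background genotype and niche; only the focal
#' locus changes to allele 1.
#'
#' @inheritParams reproduce
#' @return A list with the updated community (`state`) and the realised
#'   number of transfer events this generation (`conversions`).
#' @export
transfer_step <- function(state, p) {
  N <- attr(state, "N")
  carrier <- state$focal == 1
  C <- sum(state$count[carrier]) / N
  pr <- C * p$r
  conv <- integer(nrow(state))
  idx <- which(!carrier & state$count > 0)
  if (length(idx) > 0 && pr > 0)
    conv[idx] <- stats::rbinom(length(idx), state$count[idx], pr)
  tot <- sum(conv)
  if (tot > 0) {
    hit <- conv > 0
    st <- data.frame(
      focal = c(state$focal, rep(1, sum(hit))),
      background = c(state$background, state$background[hit]),
      niche = c(state$niche, state$niche[hit]),
      count = c(state$count - conv, conv[hit])
    )
    st <- st[st$count > 0, , drop = FALSE]
    state <- .new_community(st$focal, st$background, st$niche, st$count,
                            N, attr(state, "n"), attr(state, "next_id"))
  }
  list(state = state, conversions = tot)
}

#' Migration step
#'
#' Draws `Binomial(N, m)` cells uniformly at random (without replacement)
#' from the community and replaces each with an immigrant. Every immigrant
#' is a unique non-carrier genotype (fresh identifiers at both loci) with a
#' uniformly random niche, so carriers are replaced at expected rate
#' `m * C * N` per generation.
#'
#' @inheritParams reproduce
#' @return The community after immigration.
#' @export
migrate_step <- function(state, p) {
  N <- attr(state, "N")
  M <- stats::rbinom(1, N, p$m)
  if (M == 0) return(state)
  cells <- sample.int(N, M)
  cls <- findInterval(cells - 0.5, c(0, cumsum(state$count)))
  removed <- tabulate(cls, nrow(state))
  nid <- attr(state, "next_id")
  ids <- seq(nid, length.out = M)
  st <- data.frame(
    focal = c(state$focal, ids),
    background = c(state$background, ids),
    niche = c(state$niche, sample.int(p$n, M, replace = TRUE)),
    count = c(state$count - removed, rep(1L, M))
  )
  st <- st[st$count > 0, , drop = FALSE]
  .new_community(st$focal, st$background, st$niche, st$count,
                 N, attr(state, "n"), nid + M)
}

#' Community diversity summary
#'
#' Order-2 Hill diversities of the focal locus and the background genome of
#' an IBM community, and their ratio.
#'
#' @param state An `"ibm_community"`.
#' @return A list with `C`, `D_f`, `D_bg` and `DR`.
#' @export
community_diversity <- function(state) {
  D_f <- hill2(tapply(state$count, state$focal, sum))
  D_bg <- hill2(tapply(state$count, state$background, sum))
  list(C = sum(state$count[state$focal == 1]) / attr(state, "N"),
       D_f = D_f, D_bg = D_bg, DR = diversity_ratio(D_bg, D_f))
}

#' Run the individual-based model
#'
#' Simulates `t_end` generations with the per-generation update order
#' resource allocation -> Wright-Fisher reproduction -> horizontal transfer
#' -> migration, recording the carrier fraction, realised gene flux and the
#' order-2 diversities after the full update. The inner loop is implemented
#' in C++ over classes of identical cells; all randomness uses R's RNG
#' stream seeded from `p$seed`, so runs are reproducible bit-for-bit given
#' (parameters, seed, package version).
#'
#' @param p An [ibm_params()] object.
#' @param record_every Record metrics every this many generations (the
#'   final generation is always recorded). Recording is the only O(classes)
#'   hashing step, so thinning it speeds up long runs.
#' @return A data frame with columns `generation`, `C`, `flux_realized`
#'   (transfer events in the recorded generation), `cumulative_flux`
#'   (realised transfer events since the start), `D_f`, `D_bg`, `DR`;
#'   row 1 describes the founding community.
#' @examples
#' p <- ibm_params(N = 1000, s = 0.05, r = 1e-3, m = 0.02, C0 = 0.1,
#'                 t_end = 200, seed = 42)
#' res <- ibm_run(p)
#' tail(res, 1)
#' @export
ibm_run <- function(p, record_every = 1L) {
  stopifnot(inherits(p, "ibm_params"), record_every >= 1)
  set.seed(p$seed)
  st <- init_community(p)
  ibm_run_cpp(st$focal, st$background, st$niche, st$count,
              attr(st, "N"), attr(st, "n"), p$z, p$s, p$r, p$m,
              p$t_end, attr(st, "next_id"), as.integer(record_every))
}
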