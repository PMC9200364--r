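# Reaction-diffusion master equation engine: reaction networks, propensity
# evaluation, next-subvolume-method (NSM) event sampling, and synchronous
# multi-particle diffusion (MPD) epochs.
#
# Master equation semantics: within-subcell reactions with propensities
# a_uni = c x_A and a_bi = c x_A x_B (c already per-subcell), and diffusion
# hops to the 6 face neighbors with per-molecule propensity d_j = D_j/l_SV^2.

#' Define a reaction network
#'
#' @param species character vector of species names.
#' @param D named diffusion constants (nm^2/s); species not named are
#'   immobile.
#' @param reactions list of reactions, each a list with `name`, `c`
#'   (per-subcell propensity, 1/s), `reactants` (named integer vector,
#'   1 or 2 distinct species), `products` (named integer vector).
#' @return a `reaction_network`.
#' @examples
#' net <- reaction_network(
#'   species = c("A", "B"),
#'   reactions = list(
#'     list(name = "fwd", c = 1, reactants = c(A = 1), products = c(B = 1)),
#'     list(name = "rev", c = 3, reactants = c(B = 1), products = c(A = 1))))
#' @export
reaction_network <- function(species, D = NULL, reactions = list()) {
  J <- length(species)
  Dv <- setNames(rep(0, J), species)
  if (!is.null(D)) {
    bad <- setdiff(names(D), species)
    if (length(bad)) stop("diffusion constant for unknown species: ",
                          paste(bad, collapse = ", "))
    Dv[names(D)] <- D
  }
  M <- length(reactions)
  S <- matrix(0L, J, M, dimnames = list(species, NULL))
  cvec <- numeric(M)
  rct <- vector("list", M)
  nm <- character(M)
  for (mu in seq_len(M)) {
    r <- reactions[[mu]]
    ridx <- match(names(r$reactants), species)
    pidx <- match(names(r$products), species)
    if (anyNA(ridx) || anyNA(pidx)) {
      stop("reaction '", r$name, "' references an undefined species")
    }
    if (sum(r$reactants) > 2 || length(ridx) > 2) {
      stop("only uni- and bimolecular reactions are supported")
    }
    if (length(ridx) == 2 && any(r$reactants != 1)) {
      stop("bimolecular reactions must have two distinct reactants")
    }
    if (length(ridx) == 1 && r$reactants[1] == 2) {
      stop("homodimerization is not part of this model")
    }
    S[ridx, mu] <- S[ridx, mu] - as.integer(r$reactants)
    for (q in seq_along(pidx)) {
      S[pidx[q], mu] <- S[pidx[q], mu] + as.integer(r$products[q])
    }
    cvec[mu] <- r$c
    rct[[mu]] <- ridx
    nm[mu] <- if (is.null(r$name)) paste0("r", mu) else r$name
  }
  structure(list(species = species, D = Dv, S = S, c = cvec,
                 reactants = rct, names = nm, M = M),
            class = "reaction_network")
}

#' Propensity of one reaction given subcell counts
#'
#' @param network a `reaction_network`.
#' @param mu reaction index (or name).
#' @param counts named (or network-ordered) species counts in one subcell.
#' @return rate in 1/s: `c x_A` (unimolecular) or `c x_A x_B` (bimolecular).
#' @export
reaction_propensity <- function(network, mu, counts) {
  if (is.character(mu)) mu <- match(mu, network$names)
  if (is.na(mu) || mu < 1 || mu > network$M) stop("unknown reaction")
  ridx <- network$reactants[[mu]]
  network$c[mu] * prod(counts[ridx])
}

# All reaction propensities in every subcell: M x V matrix.
propensity_matrix <- function(network, counts) {
  V <- ncol(counts)
  A <- matrix(0, network$M, V)
  for (mu in seq_len(network$M)) {
    ridx <- network$reactants[[mu]]
    x <- counts[ridx[1], ]
    if (length(ridx) == 2) x <- x * counts[ridx[2], ]
    A[mu, ] <- network$c[mu] * x
  }
  A
}

#' One next-subvolume-method event
#'
#' Pops the subcell with the earliest scheduled reaction time, fires one of
#' its reactions with probability proportional to its propensity, applies the
#' stoichiometry, and reschedules that subcell from Exp(a0_v). The queue is a
#' named list with `times` (per-subcell absolute next-event times) kept
#' consistent by this function.
#'
#' @param lattice a `subcell_lattice` whose `counts` rows follow
#'   `network$species`.
#' @param network a `reaction_network`.
#' @param queue list with `times`; create with [nsm_init()].
#' @param t_now current time (s).
#' @return list: `lattice`, `queue`, `event` (subcell, reaction, name),
#'   `time` (absolute event time) -- or `NULL` event if the system is
#'   quiescent.
#' @export
nsm_step <- function(lattice, network, queue, t_now = 0) {
  v <- which.min(queue$times)
  tv <- queue$times[v]
  if (!is.finite(tv)) {
    return(list(lattice = lattice, queue = queue, event = NULL,
                time = Inf))
  }
  a <- propensity_vector(network, lattice$counts[, v])
  a0 <- sum(a)
  if (a0 <= 0) {  # stale schedule (counts changed externally): quiesce
    queue$times[v] <- Inf
    return(list(lattice = lattice, queue = queue, event = NULL, time = tv))
  }
  mu <- sample.int(network$M, 1, prob = a)
  lattice$counts[, v] <- lattice$counts[, v] + network$S[, mu]
  a_new <- sum(propensity_vector(network, lattice$counts[, v]))
  queue$times[v] <- if (a_new > 0) tv + rexp(1) / a_new else Inf
  list(lattice = lattice, queue = queue,
       event = list(subcell = v, reaction = mu, name = network$names[mu]),
       time = tv)
}

propensity_vector <- function(network, x) {
  vapply(seq_len(network$M), function(mu) {
    ridx <- network$reactants[[mu]]
    network$c[mu] * prod(x[ridx])
  }, numeric(1))
}

#' @rdname nsm_step
#' @param t0 initial time.
#' @export
nsm_init <- function(lattice, network, t0 = 0) {
  A <- propensity_matrix(network, lattice$counts)
  a0 <- colSums(A)
  times <- ifelse(a0 > 0, t0 + rexp(length(a0)) / a0, Inf)
  list(times = times)
}

#' One multi-particle diffusion epoch
#'
#' Every mobile molecule independently hops to one of its 6 face neighbors
#' with probability p = D_j tau / l_SV^2 per direction (stability requires
#' 6p <= 1); hops into masked-out subcells are reflected. Totals are
#' conserved exactly.
#'
#' @param lattice a `subcell_lattice` with species counts.
#' @param network a `reaction_network` (supplies D_j).
#' @param tau epoch length in s.
#' @param n_epochs number of consecutive epochs.
#' @return the lattice after diffusion.
#' @export
mpd_diffusion_step <- function(lattice, network, tau, n_epochs = 1) {
  p_hop <- network$D[lattice$species] * tau / lattice$l_SV^2
  if (any(6 * p_hop > 1)) {
    stop("tau too large: 6 D tau / l_SV^2 exceeds 1 for some species")
  }
  if (nrow(lattice$counts) == 0 || all(p_hop == 0)) return(lattice)
  lattice$counts <- mpd_epochs_cpp(lattice$counts, unname(p_hop),
                                   lattice$nbr, as.integer(n_epochs))
  lattice
}

# Stable default MPD epoch: 6p = 0.5 for the fastest species.
mpd_default_tau <- function(network, l_SV) {
  Dmax <- max(network$D)
  if (Dmax <= 0) return(Inf)
  0.5 * l_SV^2 / (6 * Dmax)
}

#' Run the RDME: NSM reaction events interleaved with MPD diffusion epochs
#'
#' Advances biological time to `bio_time`, firing reactions event-by-event
#' (NSM) and applying synchronous diffusion epochs of length `tau_epoch` to
#' the mobile species. A caller hook is invoked on events whose names are in
#' `mech_events` (the scheduler uses this to trigger mechanics updates).
#' Warns when the fastest reaction timescale is shorter than the diffusion
#' epoch (the master-equation treatment assumes diffusion is the faster
#' process).
#'
#' @param lattice a `subcell_lattice`.
#' @param network a `reaction_network`.
#' @param bio_time duration in s.
#' @param tau_epoch diffusion epoch (s); default from the 6p = 0.5 rule.
#' @param hooks optional function(event, time, lattice) called on flagged
#'   events.
#' @param mech_events character vector of reaction names that trigger the
#'   hook.
#' @param record_times times (s) at which to snapshot total species counts.
#' @return list: `lattice` (final), `events` (data.frame: time, subcell,
#'   reaction), `records` (matrix species x times), `n_events`.
#' @export
run_rdme <- function(lattice, network, bio_time, tau_epoch = NULL,
                     hooks = NULL, mech_events = character(0),
                     record_times = numeric(0)) {
  if (is.null(tau_epoch)) tau_epoch <- mpd_default_tau(network, lattice$l_SV)
  mobile <- any(network$D > 0)
  if (network$M > 0 && any(network$c > 0) && mobile) {
    if (1 / max(network$c) < tau_epoch) {
      warning("fastest reaction time is shorter than the diffusion epoch; ",
              "timescale separation is violated")
    }
  }
  queue <- nsm_init(lattice, network, t0 = 0)
  t <- 0
  next_epoch <- if (mobile) tau_epoch else Inf
  rec <- matrix(NA_real_, length(network$species), length(record_times),
                dimnames = list(network$species, NULL))
  ri <- 1
  ev_t <- numeric(0); ev_v <- integer(0); ev_mu <- integer(0)
  n_ev <- 0L
  record_upto <- function(tnew) {
    while (ri <= length(record_times) && record_times[ri] <= tnew) {
      rec[, ri] <<- rowSums(lattice$counts)
      ri <<- ri + 1
    }
  }
  while (t < bio_time) {
    tv <- suppressWarnings(min(queue$times))
    tnext <- min(tv, next_epoch, bio_time)
    record_upto(tnext)
    if (tnext >= bio_time) { t <- bio_time; break }
    if (tv <= next_epoch) {
      st <- nsm_step(lattice, network, queue, t)
      lattice <- st$lattice; queue <- st$queue; t <- st$time
      if (!is.null(st$event)) {
        n_ev <- n_ev + 1L
        ev_t <- c(ev_t, t); ev_v <- c(ev_v, st$event$subcell)
        ev_mu <- c(ev_mu, st$event$reaction)
        if (!is.null(hooks) &&
            network$names[st$event$reaction] %in% mech_events) {
          hooks(st$event, t, lattice)
        }
      }
    } else {
      lattice <- mpd_diffusion_step(lattice, network, tau_epoch)
      t <- next_epoch
      next_epoch <- next_epoch + tau_epoch
      # counts changed; propensities of every subcell may have changed
      queue <- nsm_init(lattice, network, t0 = t)
    }
  }
  record_upto(bio_time)
  list(lattice = lattice,
       events = data.frame(time = ev_t, subcell = ev_v, reaction = ev_mu,
                           name = network$names[ev_mu]),
       records = rec, record_times = record_times, n_events = n_ev)
}
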