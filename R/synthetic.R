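#' Behavioural parameters for the scan-sampling simulator
#'
#' The generator is driven by three per-class parameters plus one
#' heterogeneity knob:
#' \describe{
#'   \item{sociability}{\eqn{\sigma_c \in [0,1]}: dyad (i,j) is within arm's
#'     reach in a scan with probability \eqn{\sigma_i \sigma_j}.}
#'   \item{grooming}{\eqn{\gamma_c \in [0,1]}: probability an individual
#'     grooms (one partner) in a scan.}
#'   \item{selectivity}{\eqn{\kappa_c > 0}: Dirichlet concentration of the
#'     individual's grooming-partner preference vector; each of the N-1
#'     groupmates gets concentration \eqn{\kappa_c/(N-1)}, so small
#'     \eqn{\kappa} concentrates grooming on few partners (high disparity).}
#'   \item{individual_sd}{logit-scale SD of per-individual deviation around
#'     the class sociability and grooming propensity. Real animals of one
#'     rearing background are not behaviourally interchangeable; without
#'     this between-individual spread every class contrast would be
#'     detected with near certainty at realistic scan counts.}
#' }
#' Classes missing from a vector fall back to the `other` entry.
#'
#' @param sociability,grooming,selectivity named numeric vectors keyed by
#'   deprivation class.
#' @param individual_sd non-negative scalar (0 switches heterogeneity off).
#' @return A `behaviour_params` object.
#' @export
behaviour_params <- function(sociability, grooming, selectivity,
                             individual_sd = 0) {
  check_named <- function(x, nm, lo, hi, open_lo = FALSE) {
    if (is.null(names(x)) || any(names(x) == "")) {
      stop(nm, " must be a named vector keyed by deprivation class",
           call. = FALSE)
    }
    bad <- setdiff(names(x), deprivation_classes())
    if (length(bad) > 0) {
      stop(nm, ": unknown class label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.finite(x)) || any(x > hi) ||
        any(if (open_lo) x <= lo else x < lo)) {
      stop(nm, " out of range", call. = FALSE)
    }
  }
  check_named(sociability, "sociability", 0, 1)
  check_named(grooming, "grooming", 0, 1)
  check_named(selectivity, "selectivity", 0, Inf, open_lo = TRUE)
  if (!is.numeric(individual_sd) || length(individual_sd) != 1 ||
      individual_sd < 0) {
    stop("individual_sd must be a non-negative scalar", call. = FALSE)
  }
  structure(list(sociability = sociability, grooming = grooming,
                 selectivity = selectivity, individual_sd = individual_sd),
            class = "behaviour_params")
}

class_param <- function(x, classes) {
  out <- unname(x[classes])
  fallback <- if ("other" %in% names(x)) x[["other"]] else NA_real_
  out[is.na(out)] <- fallback
  if (anyNA(out)) {
    stop("no parameter value for class(es): ",
         paste(unique(classes[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Default study-like generator settings
#'
#' `default_behaviour_params()` encodes the class contrasts the simulator
#' emulates: grooming propensity lowest for ELD (0.05) and highest for ND
#' (0.35), partner selectivity strongest (small kappa) for ELD/LLD and
#' weakest for ND, and sociability much lower in the long-term deprived
#' classes. `default_group_specs()` mirrors the study design: 41 adults in
#' four groups — two newly re-socialised ex-laboratory-like groups of 9
#' (5 ELD + 4 LLD each) and two stable zoo-like groups of 12 and 11
#' (EMD 4 + ND 8, EMD 3 + ND 8) — with 27 females and 14 males split by
#' class as in the study population (ELD 4 F / 6 M, LLD 4/4, EMD 6/1,
#' ND 13/3).
#'
#' @return A [behaviour_params()] object, or a list of group specifications
#'   for [make_roster()].
#' @export
default_behaviour_params <- function() {
  behaviour_params(
    sociability  = c(ELD = 0.08, LLD = 0.12, EMD = 0.35, ND = 0.45,
                     LMD = 0.30, other = 0.30),
    grooming     = c(ELD = 0.05, LLD = 0.20, EMD = 0.20, ND = 0.35,
                     LMD = 0.20, other = 0.20),
    selectivity  = c(ELD = 0.3, LLD = 1, EMD = 3, ND = 30,
                     LMD = 3, other = 3),
    individual_sd = 0.8
  )
}

#' @rdname default_behaviour_params
#' @details `null_group_specs()` keeps the group sizes and class totals of
#' the default design but interleaves every class across all four groups.
#' Use it for null (all-classes-identical) simulations: with identical
#' behavioural parameters, class labels are then exchangeable, whereas
#' under the default class-segregated design a group-size effect on
#' grooming strength centrality (grooming bouts do not multiply with
#' partners available, so the /(N-1) standardization leaves a size
#' gradient) would masquerade as a class difference.
#' @export
null_group_specs <- function() {
  comp <- function(cls, n) {
    tibble::tibble(deprivation_class = cls,
                   sex = rep(c("female", "male"), length.out = length(cls)),
                   age_class = rep(c("mature", "old"), length.out = length(cls)),
                   n = n)
  }
  list(
    G1 = comp(c("ELD", "LLD", "EMD", "ND"), c(3L, 2L, 1L, 3L)),
    G2 = comp(c("ELD", "LLD", "EMD", "ND"), c(3L, 2L, 2L, 2L)),
    G3 = comp(c("ELD", "LLD", "EMD", "ND"), c(2L, 2L, 2L, 6L)),
    G4 = comp(c("ELD", "LLD", "EMD", "ND"), c(2L, 2L, 2L, 5L))
  )
}

#' @rdname default_behaviour_params
#' @export
default_group_specs <- function() {
  comp <- function(...) {
    df <- tibble::tibble(...)
    names(df) <- c("deprivation_class", "sex", "age_class", "n")
    df
  }
  list(
    EL1 = comp(c("ELD", "ELD", "LLD", "LLD"),
               c("female", "male", "female", "male"),
               c("mature", "mature", "mature", "mature"),
               c(2L, 3L, 2L, 2L)),
    EL2 = comp(c("ELD", "ELD", "LLD", "LLD"),
               c("female", "male", "female", "male"),
               c("old", "mature", "mature", "old"),
               c(2L, 3L, 2L, 2L)),
    ZO1 = comp(c("EMD", "EMD", "ND", "ND"),
               c("female", "male", "female", "male"),
               c("old", "old", "mature", "mature"),
               c(3L, 1L, 7L, 1L)),
    ZO2 = comp(c("EMD", "ND", "ND"),
               c("female", "female", "male"),
               c("old", "mature", "mature"),
               c(3L, 6L, 2L))
  )
}

#' Generate a roster from group composition specifications
#'
#' @param group_specs named list (names = group ids); each element a data
#'   frame with columns `deprivation_class`, `sex`, `age_class`, `n`
#'   giving the number of individuals per stratum.
#' @param seed integer seed (ids are deterministic; the seed is recorded so
#'   downstream callers can derive per-roster streams).
#' @return A [roster()]; individual ids are `"<group>_<k>"`.
#' @export
#' @examples
#' make_roster(default_group_specs(), seed = 1)
make_roster <- function(group_specs, seed = 1L) {
  if (is.null(names(group_specs)) || any(names(group_specs) == "")) {
    stop("group_specs must be a named list (names are group ids)",
         call. = FALSE)
  }
  rows <- lapply(names(group_specs), function(g) {
    spec <- tibble::as_tibble(group_specs[[g]])
    stopifnot(all(c("deprivation_class", "sex", "age_class", "n") %in%
                    names(spec)))
    size <- sum(spec$n)
    if (size < 2) {
      stop("group ", g, " has fewer than 2 individuals", call. = FALSE)
    }
    tibble::tibble(
      id = sprintf("%s_%02d", g, seq_len(size)),
      group_id = g,
      sex = rep(spec$sex, spec$n),
      age_class = rep(spec$age_class, spec$n),
      deprivation_class = rep(spec$deprivation_class, spec$n)
    )
  })
  out <- roster(dplyr::bind_rows(rows))
  attr(out, "seed") <- as.integer(seed)
  out
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

jitter_prob <- function(p, sd, n_draw) {
  # logit-normal spread around the class value; degenerate rates (0/1) and
  # sd = 0 pass through unchanged
  out <- p
  ok <- p > 0 & p < 1
  if (sd > 0 && any(ok)) {
    out[ok] <- inv_logit(logit(p[ok]) + stats::rnorm(sum(ok), 0, sd))
  }
  out
}

#' Draw per-individual behavioural profiles
#'
#' Realizes, once per individual, the quantities the scan simulator treats
#' as stable properties: sociability \eqn{\sigma_i}, grooming propensity
#' \eqn{\gamma_i} (class values jittered on the logit scale by
#' `individual_sd`) and the grooming-partner preference vector \eqn{\pi_i}
#' over the N-1 groupmates, drawn from a symmetric Dirichlet with total
#' concentration \eqn{\kappa_{c(i)}}. Preferences are drawn once — not per
#' scan — so partner selectivity is a property of the individual.
#'
#' @param roster a [roster()].
#' @param params a [behaviour_params()].
#' @param seed integer seed.
#' @return List with `rates` (tibble `id`, `sigma`, `gamma`) and
#'   `preferences` (named list; each element a named probability vector
#'   over the individual's groupmates).
#' @export
draw_profiles <- function(roster, params, seed) {
  stopifnot(inherits(roster, "roster"), inherits(params, "behaviour_params"))
  withr::with_seed(as.integer(seed), {
    sigma <- jitter_prob(class_param(params$sociability,
                                     roster$deprivation_class),
                         params$individual_sd, nrow(roster))
    gamma <- jitter_prob(class_param(params$grooming,
                                     roster$deprivation_class),
                         params$individual_sd, nrow(roster))
    kappa <- class_param(params$selectivity, roster$deprivation_class)
    prefs <- vector("list", nrow(roster))
    names(prefs) <- roster$id
    for (i in seq_len(nrow(roster))) {
      mates <- roster$id[roster$group_id == roster$group_id[i] &
                           roster$id != roster$id[i]]
      m <- length(mates)
      # symmetric Dirichlet(kappa/m, ..., kappa/m) via gamma draws
      g <- stats::rgamma(m, shape = kappa[i] / m, rate = 1)
      if (sum(g) <= 0) {             # numerically all-zero at tiny shape
        g <- as.numeric(seq_len(m) == sample.int(m, 1))
      }
      p <- g / sum(g)
      names(p) <- mates
      prefs[[i]] <- p
    }
    list(rates = tibble::tibble(id = roster$id, sigma = sigma, gamma = gamma),
         preferences = prefs)
  })
}

#' Simulate scan-sampling records
#'
#' Per scan: every within-group dyad (i,j) is in passive close proximity
#' with probability \eqn{\sigma_i\sigma_j}; independently, each individual
#' grooms with probability \eqn{\gamma_i}, directing the bout at a single
#' partner drawn from its preference vector \eqn{\pi_i}. Output is
#' deterministic given `seed`.
#'
#' @inheritParams draw_profiles
#' @param n_scans number of scans per group (positive integer).
#' @param seed integer seed.
#' @param period_id label for the simulated observation period.
#' @param profiles optionally, a profile realization from [draw_profiles()]
#'   to reuse (e.g. to hold individuals fixed across periods); by default
#'   profiles are drawn from `seed`.
#' @return Named list of [scan_record_set()] (one per group), with the
#'   realized `profiles` attached as an attribute.
#' @export
simulate_scans <- function(roster, params, n_scans, seed, period_id = "P1",
                           profiles = NULL) {
  stopifnot(inherits(roster, "roster"), inherits(params, "behaviour_params"))
  n_scans <- as.integer(n_scans)
  if (is.na(n_scans) || n_scans < 1) {
    stop("n_scans must be a positive integer", call. = FALSE)
  }
  if (is.null(profiles)) {
    profiles <- draw_profiles(roster, params, seed = seed)
  }
  rates <- profiles$rates
  out <- withr::with_seed(as.integer(seed) + 1L, {
    lapply(group_ids(roster), function(g) {
      ids <- roster$id[roster$group_id == g]
      n <- length(ids)
      sig <- rates$sigma[match(ids, rates$id)]
      gam <- rates$gamma[match(ids, rates$id)]
      pair <- utils::combn(n, 2)
      p_dyad <- sig[pair[1, ]] * sig[pair[2, ]]
      d <- ncol(pair)
      hits <- which(matrix(stats::runif(n_scans * d), n_scans, d) <
                      matrix(p_dyad, n_scans, d, byrow = TRUE),
                    arr.ind = TRUE)
      prox <- tibble::tibble(
        scan = as.integer(hits[, 1]), behaviour = "proximity",
        actor = ids[pair[1, hits[, 2]]], recipient = ids[pair[2, hits[, 2]]]
      )
      groom_hit <- matrix(stats::runif(n_scans * n), n_scans, n) <
        matrix(gam, n_scans, n, byrow = TRUE)
      groom_rows <- lapply(seq_len(n), function(i) {
        k <- sum(groom_hit[, i])
        if (k == 0) return(NULL)
        pref <- profiles$preferences[[ids[i]]]
        partners <- names(pref)[sample.int(length(pref), k, replace = TRUE,
                                           prob = pref)]
        tibble::tibble(scan = which(groom_hit[, i]), behaviour = "grooming",
                       actor = ids[i], recipient = partners)
      })
      scan_record_set(group_id = g, period_id = period_id, n_scans = n_scans,
                      events = dplyr::bind_rows(list(prox), groom_rows))
    })
  })
  names(out) <- group_ids(roster)
  attr(out, "profiles") <- profiles
  out
}

#' Expected network measures under the generative model
#'
#' Closed-form expectations used as the parameter-recovery oracle:
#' grooming strength centrality \eqn{100\,\gamma_i/(N-1)}; grooming
#' disparity \eqn{Y_2 = \sum_j \pi_{ij}^2} for the realized preferences;
#' expected proximity weight \eqn{w_{ij} = 100\,\sigma_i\sigma_j}, from
#' which proximity strength centrality and disparity follow.
#'
#' @inheritParams draw_profiles
#' @param profiles realized profiles from [draw_profiles()] (or the
#'   `profiles` attribute of [simulate_scans()] output).
#' @return List with `node` (tibble of per-individual expectations) and
#'   `proximity_weights` (named list of per-group expected weight
#'   matrices, percent units).
#' @export
expected_measures <- function(roster, params, profiles) {
  rates <- profiles$rates
  wmats <- lapply(group_ids(roster), function(g) {
    ids <- roster$id[roster$group_id == g]
    sig <- rates$sigma[match(ids, rates$id)]
    w <- 100 * outer(sig, sig)
    diag(w) <- 0
    dimnames(w) <- list(ids, ids)
    w
  })
  names(wmats) <- group_ids(roster)
  node <- lapply(seq_len(nrow(roster)), function(i) {
    id <- roster$id[i]
    g <- roster$group_id[i]
    w <- wmats[[g]][id, ]
    w <- w[names(w) != id]
    pref <- profiles$preferences[[id]]
    m <- length(w)
    tibble::tibble(
      id = id, group_id = g, n_group = m + 1L,
      exp_proximity_strength_centrality = sum(w) / m,
      exp_proximity_y2 = sum((w / sum(w))^2),
      exp_grooming_strength_centrality =
        100 * rates$gamma[match(id, rates$id)] / m,
      exp_grooming_y2 = sum(pref^2)
    )
  })
  list(node = dplyr::bind_rows(node), proximity_weights = wmats)
}
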