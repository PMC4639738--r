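# Brute-force oracles and tiny fixture builders shared across test files.

# A minimal two-class roster for one group.
tiny_roster <- function(n = 5, group = "G1", classes = NULL) {
  if (is.null(classes)) {
    classes <- rep(c("ND", "ELD"), length.out = n)
  }
  roster(tibble::tibble(
    id = sprintf("%s_%02d", group, seq_len(n)),
    group_id = group,
    sex = rep(c("female", "male"), length.out = n),
    age_class = rep(c("mature", "old"), length.out = n),
    deprivation_class = classes
  ))
}

# Random small scan record set (uniform random events), plus its roster.
random_instance <- function(seed, max_n = 8, max_scans = 50) {
  withr::with_seed(seed, {
    n <- sample(2:max_n, 1)
    n_scans <- sample(1:max_scans, 1)
    ros <- tiny_roster(n)
    ids <- ros$id
    rows <- list()
    for (s in seq_len(n_scans)) {
      npairs <- sample(0:3, 1)
      for (k in seq_len(npairs)) {
        pr <- sample(ids, 2)
        rows[[length(rows) + 1]] <- tibble::tibble(
          scan = s, behaviour = "proximity", actor = pr[1], recipient = pr[2])
      }
      ngroom <- sample(0:2, 1)
      for (k in seq_len(ngroom)) {
        pr <- sample(ids, 2)
        rows[[length(rows) + 1]] <- tibble::tibble(
          scan = s, behaviour = "grooming", actor = pr[1], recipient = pr[2])
      }
    }
    events <- if (length(rows) > 0) dplyr::bind_rows(rows) else
      tibble::tibble(scan = integer(), behaviour = character(),
                     actor = character(), recipient = character())
    list(roster = ros,
         records = scan_record_set("G1", "P1", n_scans, events))
  })
}

# Recompute all three measures for every individual straight from the raw
# scan list, with no network intermediate: per-scan loops and naive tallies.
oracle_measures <- function(records, roster, behaviour) {
  ids <- roster$id[roster$group_id == records$group_id]
  n <- length(ids)
  ev <- records$events[records$events$behaviour == behaviour, ]
  out <- lapply(ids, function(i) {
    partner_count <- stats::setNames(numeric(n - 1), setdiff(ids, i))
    for (s in unique(ev$scan)) {
      scan_ev <- ev[ev$scan == s, ]
      for (r in seq_len(nrow(scan_ev))) {
        if (behaviour == "proximity") {
          pair <- c(scan_ev$actor[r], scan_ev$recipient[r])
          if (i %in% pair) {
            j <- setdiff(pair, i)
            partner_count[j] <- partner_count[j] + 1
          }
        } else {
          if (scan_ev$actor[r] == i) {
            j <- scan_ev$recipient[r]
            partner_count[j] <- partner_count[j] + 1
          }
        }
      }
    }
    w <- 100 * partner_count / records$n_scans
    s_i <- sum(w)
    y2 <- if (s_i == 0) NA_real_ else sum((w / s_i)^2)
    tibble::tibble(id = i, strength_centrality = s_i / (n - 1),
                   y2 = y2, dy2 = y2 - 1 / (n - 1))
  })
  dplyr::bind_rows(out)
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(na+nb, na)
# labelings: the proportion of labelings whose min(Ua, Ub) is at most the
# observed one.
enum_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_obs <- min(u_obs, n_a * length(b) - u_obs)
  labelings <- utils::combn(length(pooled), n_a)
  u_all <- apply(labelings, 2, function(idx) {
    u <- sum(r[idx]) - n_a * (n_a + 1) / 2
    min(u, n_a * length(b) - u)
  })
  mean(u_all <= u_obs)
}

# Direct transcription of Holm's step-down rule.
hand_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[ord[i]]))
    adj[ord[i]] <- running
  }
  adj
}
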