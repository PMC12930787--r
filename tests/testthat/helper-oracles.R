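# Independent brute-force reference implementations used as oracles.
# These deliberately re-derive each rule with a different algorithm than
# the package code.

# Episode partition of sorted element dates: element i joins the episode
# of element i-1 iff its gap to EVERY feasibility check holds -- here
# re-derived by explicit cluster construction that re-checks gap against
# the previous member and span against the cluster minimum on each step.
oracle_partition <- function(dates, gap_max, span_max) {
  dates <- sort(dates)
  n <- length(dates)
  if (n == 0) return(integer(0))
  ids <- integer(n)
  cluster <- 1L
  members <- dates[1]
  ids[1] <- cluster
  if (n > 1) {
    for (i in 2:n) {
      gaps_ok <- as.integer(dates[i] - max(members)) <= gap_max
      span_ok <- as.integer(dates[i] - min(members)) <= span_max
      if (gaps_ok && span_ok) {
        members <- c(members, dates[i])
      } else {
        cluster <- cluster + 1L
        members <- dates[i]
      }
      ids[i] <- cluster
    }
  }
  ids
}

# Device association by full run enumeration: build every maximal run of
# qualifying device-days and test whether onset or the preceding day sits
# in a run at depth >= min_days from the run start.
oracle_device_assoc <- function(dev_days, onset, min_days = 3L) {
  dev_days <- sort(unique(dev_days))
  if (length(dev_days) == 0) return(FALSE)
  run_id <- cumsum(c(1L, as.integer(diff(dev_days) > 1)))
  for (r in split(dev_days, run_id)) {
    for (offset in c(0L, 1L)) {
      d <- onset - offset
      if (d %in% r && as.integer(d - min(r)) + 1L >= min_days) return(TRUE)
    }
  }
  FALSE
}

# Greedy left-to-right repeat suppression over (infection_date,
# episode_start, episode_end) triples of one patient and body system.
# Returns the indices kept.
oracle_suppress <- function(inf_dates, ep_starts, ep_ends,
                            repeat_min = 14L, symptom_free_min = 1L) {
  ord <- order(inf_dates)
  kept <- integer(0)
  kept_date <- NULL
  last_symptom <- NULL
  for (i in ord) {
    ok <- is.null(kept_date) ||
      (as.integer(inf_dates[i] - kept_date) >= repeat_min &&
         as.integer(ep_starts[i] - last_symptom) - 1L >= symptom_free_min)
    if (ok) {
      kept <- c(kept, i)
      kept_date <- inf_dates[i]
      last_symptom <- ep_ends[i]
    } else {
      last_symptom <- max(last_symptom, ep_ends[i])
    }
  }
  kept
}

# Rule-aware expected line list for a simulated cohort: applies the
# surveillance rules (follow-up merging, infection-date, late-onset, SSI
# attribution, device association, repeat suppression, MDRO flag) to the
# planted truth with plain loops, independently of the engine.
oracle_expected_linelist <- function(sim,
                                     definitions = default_definitions()) {
  par <- definitions$parameters
  cohort <- sim$cohort
  truth <- sim$truth
  rows <- list()
  for (pid in unique(truth$patient_id)) {
    p <- cohort$patients[cohort$patients$patient_id == pid, ]
    ev <- truth[truth$patient_id == pid, ]
    ev$inf_date <- pmin(ev$symptom_onset_date, ev$primary_specimen_date,
                        na.rm = TRUE)
    # late onset at date granularity
    dol <- as.integer(ev$inf_date - p$birth_date) + 1L
    ev <- ev[dol >= (par$late_onset_hours %/% 24) + 1L, , drop = FALSE]
    if (nrow(ev) == 0) next
    # SSI attribution (most recent qualifying surgery)
    sg <- cohort$surgeries[cohort$surgeries$patient_id == pid, ]
    ev$hai_type <- ev$planted_type
    ev$linked <- NA_character_
    drop <- logical(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      if (ev$body_system[i] != "surgical_site") next
      delta <- as.integer(ev$inf_date[i] - sg$date)
      win <- ifelse(sg$implant & ev$depth[i] %in% c("deep", "organ_space"),
                    par$ssi_implant_window_days, par$ssi_window_days)
      ok <- delta >= 0 & delta <= win
      if (!any(ok)) {
        drop[i] <- TRUE
      } else {
        pick <- which(ok)[which.max(sg$date[ok])]
        ev$linked[i] <- sg$surgery_id[pick]
        ev$hai_type[i] <- paste0("ssi_", ev$depth[i])
      }
    }
    ev <- ev[!drop, , drop = FALSE]
    if (nrow(ev) == 0) next
    # repeat suppression per body system, with organism merging
    ex <- cohort$exposures[cohort$exposures$patient_id == pid, ]
    for (bs in unique(ev$body_system)) {
      sub <- ev[ev$body_system == bs, , drop = FALSE]
      kept_idx <- oracle_suppress(sub$inf_date, sub$inf_date,
                                  sub$last_element_date,
                                  par$repeat_min_days,
                                  par$symptom_free_min_days)
      # merge organisms/markers of suppressed events into preceding kept one
      ord <- order(sub$inf_date)
      owner <- rep(NA_integer_, nrow(sub))
      current <- NA_integer_
      for (i in ord) {
        if (i %in% kept_idx) current <- i
        owner[i] <- current
      }
      for (k in kept_idx) {
        grp <- which(owner == k)
        orgs <- unlist(lapply(sub$organisms[grp], function(o) {
          if (is.na(o)) character(0) else strsplit(o, ";")[[1]]
        }))
        mks <- unlist(lapply(sub$markers[grp], function(o) {
          if (is.na(o)) character(0) else strsplit(o, ";")[[1]]
        }))
        orgs <- sort(unique(orgs)); mks <- sort(unique(mks))
        # device association from the final exposure grid
        dev <- "none"
        dev_cols <- if (bs == "bloodstream") {
          c(CVC = "cvc_hours", PVC = "pvc_hours")
        } else if (bs == "respiratory") {
          c(INV = "inv_hours", NIV = "niv_hours")
        } else {
          c()
        }
        for (dn in names(dev_cols)) {
          dd <- ex$date[ex[[dev_cols[[dn]]]] >= par$device_day_min_hours]
          if (oracle_device_assoc(dd, sub$inf_date[k],
                                  par$device_assoc_min_days)) {
            dev <- dn
            break
          }
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          patient_id = pid, hai_type = sub$hai_type[k],
          infection_date = sub$inf_date[k], device_association = dev,
          linked_surgery_id = sub$linked[k],
          organisms = if (length(orgs)) paste(orgs, collapse = ";") else NA_character_,
          resistance_markers = if (length(mks)) paste(mks, collapse = ";") else NA_character_,
          is_mdro = length(mks) > 0,
          n_merged = length(grp) - 1L
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (ncol(out) == 0) {
    out <- tibble::tibble(
      patient_id = character(0), hai_type = character(0),
      infection_date = as.Date(character(0)),
      device_association = character(0), linked_surgery_id = character(0),
      organisms = character(0), resistance_markers = character(0),
      is_mdro = logical(0), n_merged = integer(0)
    )
  }
  out[order(out$patient_id, out$infection_date, out$hai_type,
            method = "radix"), ]
}
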