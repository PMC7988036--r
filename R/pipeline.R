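#' Write a simulated dataset to plain-text files
#'
#' Per session: `tracking_<S>.csv` (`t,x,y`), `spikes_<S>.csv`
#' (`cell_id,t`) and `events_<S>.csv` (`t,type,door,side,crossed,
#' goal_box`). The protocol, configuration and planted ground truth go to
#' `protocol.json` and `truth.json`.
#'
#' @param dataset A [simulate_sequence()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fourrooms_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in names(dataset$sessions)) {
    ses <- dataset$sessions[[s]]
    utils::write.csv(ses$trajectory,
                     file.path(dir, paste0("tracking_", s, ".csv")),
                     row.names = FALSE)
    spk <- dataset$spikes[[s]]
    spk_df <- data.frame(
      cell_id = rep(seq_along(spk), lengths(spk)),
      t = unlist(spk))
    utils::write.csv(spk_df, file.path(dir, paste0("spikes_", s, ".csv")),
                     row.names = FALSE)
    ev <- rbind(
      data.frame(t = ses$events$bells$t, type = "bell", door = NA,
                 side = NA, crossed = NA, goal_box = ses$events$bells$goal),
      if (nrow(ses$events$pushes))
        data.frame(t = ses$events$pushes$t, type = "push",
                   door = ses$events$pushes$door,
                   side = ses$events$pushes$side,
                   crossed = ses$events$pushes$crossed, goal_box = NA))
    ev <- ev[order(ev$t), ]
    utils::write.csv(ev, file.path(dir, paste0("events_", s, ".csv")),
                     row.names = FALSE)
  }
  pr <- dataset$protocol
  jsonlite::write_json(list(
    sequence = pr$sequence, goal_list = pr$goal_list,
    locked_door = pr$locked_door, cycle = pr$cycle,
    box_side = pr$geometry$box_side, door_size = pr$geometry$door_size),
    file.path(dir, "protocol.json"), auto_unbox = TRUE, pretty = TRUE)
  truth <- lapply(dataset$truth$cells, function(cl) {
    list(cell = cl$cell, repeat_k = cl$repeat_k,
         remap_o2_c1 = cl$remap_o2_c1, width_us = cl$width_us,
         sessions = lapply(cl$sessions, function(f) as.list(f)))
  })
  jsonlite::write_json(list(seed = dataset$seed, cells = truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Dataset directory.
#' @param sessions Session labels to read.
#' @return List with `sessions` (trajectory/events per session), `spikes`
#'   and `protocol` (reconstructed [session_protocol()]).
#' @export
read_dataset <- function(dir, sessions = c("O1", "O2", "C1", "C2", "O3")) {
  pj <- jsonlite::read_json(file.path(dir, "protocol.json"),
                            simplifyVector = TRUE)
  protocol <- session_protocol(
    pj$sequence, goal_list = pj$goal_list,
    locked_door = if (!is.null(pj$locked_door) && !is.na(pj$locked_door))
      pj$locked_door else "A-B",
    cycle = if (!is.null(pj$cycle) && !is.na(pj$cycle)) pj$cycle else "cw")
  ses <- list(); spikes <- list()
  for (s in sessions) {
    tr <- utils::read.csv(file.path(dir, paste0("tracking_", s, ".csv")))
    ev <- utils::read.csv(file.path(dir, paste0("events_", s, ".csv")))
    bells <- ev[ev$type == "bell", c("t", "goal_box")]
    names(bells) <- c("t", "goal")
    pushes <- ev[ev$type == "push", c("t", "door", "side", "crossed")]
    rownames(bells) <- rownames(pushes) <- NULL
    ses[[s]] <- list(trajectory = tr,
                     events = list(bells = bells, pushes = pushes),
                     duration = max(tr$t))
    sp <- utils::read.csv(file.path(dir, paste0("spikes_", s, ".csv")))
    n_cells <- max(sp$cell_id)
    spikes[[s]] <- lapply(seq_len(n_cells), function(ci)
      sort(sp$t[sp$cell_id == ci]))
  }
  list(sessions = ses, spikes = spikes, protocol = protocol)
}

#' Run the full analysis pipeline on one dataset
#'
#' Behavior segmentation and connectivity-knowledge metrics, per-cell rate
#' maps with spatial information and place-cell classification, session/
#' doorway/cross-box correlation analyses, Fuhs rate remapping, place-field
#' detection with the overrepresentation tests, and cross-session Bayesian
#' decoding (O1 -> O2 and O2 -> C1; skipped with a log entry when fewer
#' than 15 place cells are available).
#'
#' @param dataset A [simulate_sequence()] result (or [read_dataset()]
#'   output augmented with a `config`; simulated datasets carry everything
#'   needed).
#' @param seed Seed for the analysis-stage shuffles.
#' @param si_shuffles Spike-shift shuffles per cell (default 100).
#' @param stages Character subset of
#'   `c("behavior","maps","fields","remapping","decoding")`.
#' @return List of per-stage result objects; `log` records skipped stages.
#' @export
analyze_dataset <- function(dataset, seed = 1, si_shuffles = 100,
                            stages = c("behavior", "maps", "fields",
                                       "remapping", "decoding")) {
  set.seed(seed)
  protocol <- dataset$protocol
  geom <- protocol$geometry
  labs <- names(dataset$sessions)
  n_cells <- length(dataset$spikes[[1]])
  res <- list(log = character(0))
  grid <- map_grid(geom)

  seg <- lapply(labs, function(s)
    segment_behavior(dataset$sessions[[s]]$trajectory,
                     dataset$sessions[[s]]$events, geom))
  names(seg) <- labs

  if ("behavior" %in% stages) {
    cleaned <- lapply(labs, function(s)
      clean_event_flags(dataset$sessions[[s]]$events,
                        dataset$sessions[[s]]$trajectory, geom))
    names(cleaned) <- labs
    durations <- vapply(labs, function(s)
      dataset$sessions[[s]]$duration / 60, numeric(1))
    pushes_by_session <- lapply(cleaned, function(cl) cl$events$pushes)
    trials <- do.call(rbind, lapply(labs, function(s)
      build_trials(s, cleaned[[s]]$events, seg[[s]]$visits,
                   cleaned[[s]]$rejected)))
    res$behavior <- list(
      visits = lapply(seg, `[[`, "visits"),
      push_rates = push_rate_analysis(pushes_by_session, protocol, durations),
      push_rates_quarters = push_rate_analysis(pushes_by_session, protocol,
                                               durations, quarters = TRUE),
      bell = lapply(labs, function(s)
        bell_response_metrics(dataset$sessions[[s]]$trajectory,
                              cleaned[[s]]$events,
                              dataset$sessions[[s]]$duration,
                              n_shuffles = 200)),
      first_choice = first_choice_accuracy(trials, protocol),
      trials = trials,
      rejected = lapply(cleaned, `[[`, "rejected"))
  }

  # per-cell maps are needed by every downstream stage
  maps_all <- list(); maps_forage <- list(); maps_goal <- list()
  box_maps <- list(); doorway_maps <- list()
  for (ci in seq_len(n_cells)) {
    maps_all[[ci]] <- list(); maps_forage[[ci]] <- list()
    maps_goal[[ci]] <- list(); box_maps[[ci]] <- list()
    doorway_maps[[ci]] <- list()
    for (si in seq_along(labs)) {
      s <- labs[si]
      tr <- dataset$sessions[[s]]$trajectory
      spk <- dataset$spikes[[s]][[ci]]
      maps_all[[ci]][[si]] <- rate_map(tr, spk, grid)
      maps_forage[[ci]][[si]] <- rate_map(tr, spk, grid, mode = "foraging",
                                          mode_labels = seg[[s]]$mode)
      maps_goal[[ci]][[si]] <- rate_map(tr, spk, grid, mode = "goal_directed",
                                        mode_labels = seg[[s]]$mode)
      bd <- box_and_doorway_maps(tr, spk, geom, mode = "foraging",
                                 mode_labels = seg[[s]]$mode)
      box_maps[[ci]][[si]] <- bd$box_maps
      doorway_maps[[ci]][[si]] <- bd$doorway
    }
  }

  si_tab <- NULL
  if ("maps" %in% stages) {
    rows <- list()
    for (ci in seq_len(n_cells)) {
      rates <- vapply(seq_along(labs), function(si) {
        dur <- dataset$sessions[[labs[si]]]$duration
        length(dataset$spikes[[labs[si]]][[ci]]) / dur
      }, numeric(1))
      si_vals <- numeric(length(labs)); si_sig <- logical(length(labs))
      best <- which.max(rates)
      for (si in seq_along(labs)) {
        if (si == best) {
          sh <- spike_shift_shuffle(
            dataset$sessions[[labs[si]]]$trajectory,
            dataset$spikes[[labs[si]]][[ci]], grid,
            dataset$sessions[[labs[si]]]$duration, n = si_shuffles)
          si_vals[si] <- sh$observed; si_sig[si] <- sh$significant
        } else {
          si_vals[si] <- spatial_information(maps_all[[ci]][[si]])
          si_sig[si] <- NA
        }
      }
      width <- if (!is.null(dataset$truth))
        dataset$truth$cells[[ci]]$width_us else NA
      cls <- classify_place_cell(rates, si_vals, si_sig, width)
      rows[[ci]] <- data.frame(cell = ci, mean_rate_best = rates[best],
                               si_best = si_vals[best],
                               si_significant = si_sig[best],
                               width_us = width,
                               place_cell = cls$place_cell,
                               reasons = paste(cls$reasons, collapse = ";"))
    }
    si_tab <- do.call(rbind, rows)
    res$cells <- si_tab
  }

  field_tables <- NULL
  if ("fields" %in% stages) {
    pfs_by_session <- lapply(seq_along(labs), function(si) {
      per_cell <- lapply(seq_len(n_cells), function(ci)
        detect_fields(maps_forage[[ci]][[si]]))
      do.call(rbind, lapply(seq_len(n_cells), function(ci) {
        f <- fields_near_doors(per_cell[[ci]], geom)
        if (nrow(f)) cbind(cell = ci, f) else NULL
      }))
    })
    names(pfs_by_session) <- labs
    field_tables <- lapply(pfs_by_session, function(f)
      if (is.null(f)) data.frame(cx = numeric(0), cy = numeric(0)) else f)
    dwells <- lapply(seq_along(labs), function(si)
      rate_map(dataset$sessions[[labs[si]]]$trajectory, numeric(0),
               grid)$dwell)
    over <- tryCatch(
      overrepresentation_tests(field_tables, dwells, grid, protocol),
      error = function(e) {
        res$log <<- c(res$log, paste("overrepresentation skipped:",
                                     conditionMessage(e)))
        NULL
      })
    res$fields <- list(tables = field_tables, overrepresentation = over,
                       counts = vapply(field_tables, nrow, integer(1)))
  }

  if ("remapping" %in% stages) {
    use <- if (!is.null(si_tab)) which(si_tab$place_cell) else
      seq_len(n_cells)
    if (!length(use)) use <- seq_len(n_cells)
    sess_corr <- session_correlation_analysis(maps_forage[use])
    doorway <- doorway_correlation_analysis(doorway_maps[use], protocol)
    fuhs <- data.frame(
      cell = use,
      o1_o2 = vapply(use, function(ci)
        fuhs_metric(maps_forage[[ci]][[1]], maps_forage[[ci]][[2]]),
        numeric(1)),
      o2_c1 = vapply(use, function(ci)
        fuhs_metric(maps_forage[[ci]][[2]], maps_forage[[ci]][[3]]),
        numeric(1)))
    cross_box <- cross_box_analysis(lapply(use, function(ci)
      box_maps[[ci]][[2]]))
    indiv <- tryCatch(
      classify_individual_remapping(list(maps_forage[use])),
      error = function(e) {
        res$log <<- c(res$log, paste("individual remapping skipped:",
                                     conditionMessage(e)))
        NULL
      })
    fvg <- lapply(seq_along(labs), function(si)
      foraging_vs_goal_remapping(
        lapply(use, function(ci) maps_forage[[ci]][[si]]),
        lapply(use, function(ci) maps_goal[[ci]][[si]]), n = 500))
    names(fvg) <- labs
    res$remapping <- list(session = sess_corr, doorway = doorway,
                          fuhs = fuhs, cross_box = cross_box,
                          individual = indiv, foraging_vs_goal = fvg)
  }

  if ("decoding" %in% stages) {
    use <- if (!is.null(si_tab)) which(si_tab$place_cell) else
      seq_len(n_cells)
    res$decoding <- list()
    for (pair in list(c(1, 2), c(2, 3))) {
      key <- paste0(labs[pair[1]], "->", labs[pair[2]])
      if (length(use) < 15) {
        res$log <- c(res$log, paste("decoding", key,
                                    "skipped: fewer than 15 place cells"))
        next
      }
      model <- fit_decoder(lapply(use, function(ci)
        maps_all[[ci]][[pair[1]]]), train_label = labs[pair[1]],
        geometry = geom)
      res$decoding[[key]] <- decode_session(
        model, dataset$sessions[[labs[pair[2]]]]$trajectory,
        dataset$spikes[[labs[pair[2]]]][use], test_label = labs[pair[2]])
    }
  }
  res$maps <- list(all = maps_all, foraging = maps_forage, goal = maps_goal,
                   box = box_maps, doorway = doorway_maps, grid = grid)
  res$segmentation <- seg
  res
}

#' Human-readable summary of pipeline results
#'
#' Prints the headline tables of each completed stage, including the
#' chance levels the figures are read against (1/3 for first foraging
#' choices, 1/16 quadrants for decoding).
#'
#' @param results An [analyze_dataset()] result.
#' @return `results`, invisibly.
#' @export
report_results <- function(results) {
  cat("== Four-room analysis report ==\n")
  if (!is.null(results$behavior)) {
    fc <- results$behavior$first_choice
    cat("\n-- Behavior --\n")
    cat(sprintf("First foraging choices: %d/%d correct (%.1f%%; chance 33%%)\n",
                fc$foraging$n_correct, fc$foraging$n,
                100 * fc$foraging$proportion))
    if (!is.null(fc$doors)) {
      cat("Optimal first pushes by start-goal distance (chance 50%):\n")
      print(fc$doors, row.names = FALSE)
    }
    pr <- results$behavior$push_rates
    agg <- stats::aggregate(rate ~ session + group, pr, mean)
    cat("Push rates (pushes/door-side/min):\n")
    print(agg, row.names = FALSE)
  }
  if (!is.null(results$cells)) {
    cat(sprintf("\n-- Units --\n%d/%d cells classified as place cells\n",
                sum(results$cells$place_cell), nrow(results$cells)))
  }
  if (!is.null(results$fields)) {
    cat("\n-- Place fields --\nFields per session:\n")
    print(results$fields$counts)
  }
  if (!is.null(results$remapping)) {
    cat("\n-- Remapping --\nMean session-correlation matrix:\n")
    print(round(results$remapping$session$mean_matrix, 3))
    ct <- results$remapping$session$contrast
    cat(sprintf("O1-O2 mean r = %.3f, O2-C1 mean r = %.3f\n",
                mean(ct$o1_o2, na.rm = TRUE), mean(ct$o2_c1, na.rm = TRUE)))
  }
  if (!is.null(results$decoding) && length(results$decoding)) {
    cat("\n-- Decoding (chance 1/16 = 0.0625) --\n")
    for (key in names(results$decoding)) {
      cat(key, ":\n")
      print(results$decoding[[key]]$summary, row.names = FALSE)
    }
  }
  if (length(results$log)) {
    cat("\n-- Log --\n")
    cat(paste(results$log, collapse = "\n"), "\n")
  }
  invisible(results)
}
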