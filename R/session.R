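#' Parse a session command
#'
#' Commands mirror the simulator's voice-command set (`select`, `scan`,
#' `next`, `previous`) plus the plumbing verbs `move_needle` (with a tip
#' position and axis payload) and `end`. `move_needle` lines have the form
#' `move_needle tx ty tz ax ay az` (world tip mm, axis direction).
#'
#' @param line a single command line.
#' @param line_number optional line number used in parse-error messages.
#' @return list with `verb` and, for `move_needle`, `needle`
#'   (a [needle_state()]).
#' @export
parse_command <- function(line, line_number = NA) {
  where <- if (is.na(line_number)) "" else sprintf(" (line %d)", line_number)
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(tok) == 0 || tok[1] == "") {
    abort_ct("parse_error", "empty command%s", where)
  }
  verb <- tok[1]
  if (verb %in% c("select", "scan", "next", "previous", "end")) {
    if (length(tok) != 1) {
      abort_ct("parse_error", "command '%s' takes no arguments%s", verb, where)
    }
    return(list(verb = verb))
  }
  if (verb == "move_needle") {
    if (length(tok) != 7) {
      abort_ct("parse_error",
               "move_needle needs 6 numbers (tx ty tz ax ay az)%s", where)
    }
    vals <- suppressWarnings(as.numeric(tok[2:7]))
    if (any(is.na(vals))) {
      abort_ct("parse_error", "non-numeric move_needle argument%s", where)
    }
    return(list(verb = "move_needle",
                needle = needle_state(vals[1:3], vals[4:6])))
  }
  abort_ct("parse_error", "unknown command '%s'%s", verb, where)
}

#' Start a biopsy training session
#'
#' @param volume A [ct_volume()] with labeled targets.
#' @param targets list of [target_lesion()] in the order they are attempted
#'   (conventionally beginner first, then expert).
#' @param params A [scan_params()].
#' @param hit_tolerance hit distance tolerance in mm; the default 0 requires
#'   the tip to lie inside the labeled lesion.
#' @param needle_geom A [needle_model()] for slice rendering.
#' @return An object of class `biopsy_session`.
#' @export
new_session <- function(volume, targets, params = scan_params(),
                        hit_tolerance = 0, needle_geom = needle_model()) {
  stopifnot(inherits(volume, "ct_volume"))
  if (length(targets) == 0) abort_ct("validation_error", "at least one target required")
  for (t in targets) stopifnot(inherits(t, "target_lesion"))
  structure(list(
    volume = volume, targets = targets, params = params,
    hit_tolerance = hit_tolerance, needle_geom = needle_geom,
    selected = FALSE, needle = NULL, slice_index = 0L,
    scan_count = 0L, step_count = 0L,
    history = data.frame(step = integer(), verb = character()),
    target_idx = 1L, targets_hit = 0L,
    per_scan_distance = numeric(), completed = FALSE, closed = FALSE
  ), class = "biopsy_session")
}

active_target <- function(session) session$targets[[session$target_idx]]

#' Test whether the needle tip has reached a target
#'
#' The distance is [lesion_distance()] from the tip to the target's label
#' mask; a hit is registered when the tip's containing voxel carries the
#' label, or the distance is within `tolerance`.
#'
#' @param needle A [needle_state()].
#' @param volume A [ct_volume()].
#' @param target A [target_lesion()].
#' @param tolerance hit tolerance in mm (default 0: inside the lesion).
#' @return list with `hit` (logical) and `distance` (mm).
#' @export
check_hit <- function(needle, volume, target, tolerance = 0) {
  d <- lesion_distance(volume, target$label_id, needle$tip)
  list(hit = d <= tolerance, distance = d)
}

#' Advance the session state machine by one command
#'
#' `select` arms the needle tool; `move_needle` (only after `select`)
#' updates the tracked needle; `scan` increments the scan counter, picks the
#' slab nearest the tip, renders the simulated slice and evaluates the hit
#' rule; `next`/`previous` navigate slices; `end` closes the session. On a
#' hit, the next configured target becomes active, or the session completes
#' if it was the last.
#'
#' @param session A `biopsy_session`.
#' @param cmd a command from [parse_command()] (or an equivalent list).
#' @return list with `session` (updated state) and `slice` (a
#'   `simulated_slice` for `scan` commands, else `NULL`).
#' @export
session_step <- function(session, cmd) {
  if (session$closed || session$completed) {
    abort_ct("session_closed_error", "session is closed; no further commands accepted")
  }
  session$step_count <- session$step_count + 1L
  session$history <- rbind(session$history,
                           data.frame(step = session$step_count, verb = cmd$verb))
  slice <- NULL
  switch(cmd$verb,
    select = {
      session$selected <- TRUE
    },
    move_needle = {
      if (!session$selected) {
        abort_ct("command_order_error",
                 "move_needle before select: the needle tool is not selected")
      }
      session$needle <- cmd$needle
    },
    scan = {
      session$scan_count <- session$scan_count + 1L
      if (!is.null(session$needle)) {
        session$slice_index <- slice_for_needle(session$volume, session$needle,
                                                session$params)
        slice <- render_slice(session$volume, session$slice_index,
                              session$needle, session$params,
                              session$needle_geom)
        res <- check_hit(session$needle, session$volume, active_target(session),
                         session$hit_tolerance)
        session$per_scan_distance <- c(session$per_scan_distance, res$distance)
        if (res$hit) {
          session$targets_hit <- session$targets_hit + 1L
          if (session$target_idx < length(session$targets)) {
            session$target_idx <- session$target_idx + 1L
          } else {
            session$completed <- TRUE
            session$closed <- TRUE
          }
        }
      } else {
        slice <- render_slice(session$volume, session$slice_index,
                              NULL, session$params, session$needle_geom)
        session$per_scan_distance <- c(session$per_scan_distance, NA_real_)
      }
    },
    `next` = {
      session$slice_index <- next_slice(session$slice_index, session$volume,
                                        session$params)
    },
    previous = {
      session$slice_index <- previous_slice(session$slice_index, session$volume,
                                            session$params)
    },
    end = {
      session$closed <- TRUE
    },
    abort_ct("parse_error", "unknown verb '%s'", cmd$verb)
  )
  list(session = session, slice = slice)
}

#' Summarise a finished (or abandoned) session
#'
#' @param session A `biopsy_session`.
#' @return An object of class `session_report`: `scan_count`, `total_steps`,
#'   `final_distance_mm` (tip to the active target; `NA` if the needle was
#'   never placed), `hit` (active target reached), `per_scan_distance_mm`,
#'   `difficulty` attempted, and `targets_hit`.
#' @export
session_report <- function(session) {
  final_d <- if (is.null(session$needle)) NA_real_ else {
    check_hit(session$needle, session$volume, active_target(session),
              session$hit_tolerance)$distance
  }
  structure(list(
    scan_count = session$scan_count,
    total_steps = session$step_count,
    final_distance_mm = final_d,
    hit = session$completed,
    per_scan_distance_mm = session$per_scan_distance,
    difficulty = active_target(session)$difficulty,
    targets_hit = session$targets_hit
  ), class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat("<session_report>\n")
  cat(sprintf("  difficulty attempted: %s\n", x$difficulty))
  cat(sprintf("  scans: %d  steps: %d  targets hit: %d\n",
              x$scan_count, x$total_steps, x$targets_hit))
  cat(sprintf("  hit: %s  final tip-to-target distance: %s mm\n",
              x$hit, format(round(x$final_distance_mm, 2))))
  invisible(x)
}

#' Replay a scripted session
#'
#' Reads a plain-text command file (one command per line; blank lines and
#' `#` comments ignored), replays it through [session_step()] starting at
#' the first target, and returns the [session_report()]. Deterministic: the
#' same script, volume and parameters always give the same report.
#'
#' @param script path to a command file, or a character vector of lines.
#' @param volume A [ct_volume()].
#' @param targets list of [target_lesion()] (beginner first by convention).
#' @param params A [scan_params()].
#' @param hit_tolerance hit tolerance in mm.
#' @param needle_geom A [needle_model()].
#' @param on_slice optional callback `function(slice, scan_number)` invoked
#'   for every rendered scan (used by the CLI to export slice images).
#' @return A `session_report`.
#' @export
run_script <- function(script, volume, targets, params = scan_params(),
                       hit_tolerance = 0, needle_geom = needle_model(),
                       on_slice = NULL) {
  lines <- if (length(script) == 1 && file.exists(script)) {
    readLines(script, warn = FALSE)
  } else {
    as.character(script)
  }
  session <- new_session(volume, targets, params, hit_tolerance, needle_geom)
  for (i in seq_along(lines)) {
    raw_line <- sub("#.*$", "", lines[i])
    if (trimws(raw_line) == "") next
    cmd <- parse_command(raw_line, line_number = i)
    out <- session_step(session, cmd)
    session <- out$session
    if (!is.null(out$slice) && !is.null(on_slice)) {
      on_slice(out$slice, session$scan_count)
    }
    if (session$closed) break
  }
  session_report(session)
}
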