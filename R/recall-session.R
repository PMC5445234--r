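SESSION_STATES <- c("meal_listing", "item_entry", "detail_entry", "review", "finalized")

state_index <- function(s) match(s, SESSION_STATES)

advance_state <- function(session, to) {
  if (state_index(to) > state_index(session$state)) session$state <- to
  session
}

check_not_finalized <- function(session, op) {
  if (identical(session$state, "finalized")) {
    stop(sprintf("session is finalized; %s is not allowed", op), call. = FALSE)
  }
}

#' Start a recall session
#'
#' Opens the multiple-pass recall of one participant-day. The session is a
#' forward-only state machine: meal quick-listing, item entry, detail entry
#' (probes, linked foods, portions), review, finalized. Each pass of the
#' interview corresponds to a state with preconditions rather than a screen,
#' so a whole session can be driven non-interactively by an answer script.
#'
#' @param participant_id Participant identifier.
#' @param recall_date The day being recalled (Date or "YYYY-MM-DD" string);
#'   the recall covers that calendar day, midnight to midnight.
#' @return A `recall_session` in state `meal_listing` with no meals.
#' @export
start_session <- function(participant_id, recall_date) {
  stopifnot(nzchar(participant_id))
  structure(
    list(
      participant_id = as.character(participant_id),
      recall_date = as.character(recall_date),
      meals = list(),
      supplements = list(),
      forgotten_foods_reviewed = FALSE,
      usual_intake_flag = "unknown",
      state = "meal_listing",
      last_prompts = NULL
    ),
    class = "recall_session"
  )
}

#' Add a meal or snack to the quick list
#'
#' Meals are kept sorted by time of consumption; times are "HH:MM" on the
#' 24-hour clock.
#'
#' @param session A `recall_session` in state `meal_listing` or `item_entry`.
#' @param meal_name Free-text name ("breakfast", "snack", ...).
#' @param time "HH:MM" within 00:00-23:59.
#' @param location Preparation location: one of `"home"`,
#'   `"restaurant/takeaway"`, `"workplace/other"`, `"unknown"`.
#' @return The updated session.
#' @export
add_meal <- function(session, meal_name, time, location = "unknown") {
  stopifnot(inherits(session, "recall_session"))
  check_not_finalized(session, "add_meal")
  if (!session$state %in% c("meal_listing", "item_entry")) {
    stop("meals can only be added during meal listing or item entry", call. = FALSE)
  }
  location <- match.arg(location, c("home", "restaurant/takeaway", "workplace/other", "unknown"))
  mins <- parse_hhmm(time)
  if (is.na(mins)) stop(sprintf("unparseable meal time '%s' (expected HH:MM)", time), call. = FALSE)
  session$meals <- c(session$meals, list(list(
    meal_name = meal_name, time = time, location = location, food_entries = list()
  )))
  times <- vapply(session$meals, function(m) parse_hhmm(m$time), numeric(1))
  session$meals <- session$meals[order(times)]
  session
}

new_food_entry <- function(food_id, linked_parent = NULL) {
  list(
    food_id = food_id,
    original_food_id = food_id,
    probe_answers = list(),
    probe_tags = character(0),
    pending_probes = character(0),
    portion_response = NULL,
    resolved_weight_g = NA_real_,
    linked_parent = linked_parent
  )
}

#' Add a food or drink item to a meal
#'
#' Appends the item and surfaces its completeness-of-collection prompts: the
#' probe questions that must be answered before finalization, and the linked
#' foods commonly consumed with it, offered for acceptance via
#' [accept_linked()]. Retrieve the prompts with [pending_prompts()].
#'
#' @param session A `recall_session` (meal listing through detail entry).
#' @param meal_index Position of the meal in the current time-sorted order.
#' @param food_id Item to add; must exist in `db`.
#' @param db The `food_db` in use.
#' @param linked_parent Internal; set by [accept_linked()].
#' @return The updated session; `pending_prompts(session)` holds the probes
#'   and linked candidates for the item just added.
#' @export
add_food <- function(session, meal_index, food_id, db, linked_parent = NULL) {
  stopifnot(inherits(session, "recall_session"), inherits(db, "food_db"))
  check_not_finalized(session, "add_food")
  if (!session$state %in% c("meal_listing", "item_entry", "detail_entry")) {
    stop("foods can only be added before review", call. = FALSE)
  }
  if (meal_index < 1 || meal_index > length(session$meals)) {
    stop(sprintf("bad meal index %s (session has %d meals)", meal_index, length(session$meals)),
      call. = FALSE
    )
  }
  if (!food_id %in% db$foods$food_id) {
    stop(sprintf("unknown food_id '%s'", food_id), call. = FALSE)
  }
  entry <- new_food_entry(food_id, linked_parent)
  probe_ids <- db$foods$probe_ids[[match(food_id, db$foods$food_id)]]
  entry$pending_probes <- probe_ids
  session$meals[[meal_index]]$food_entries <-
    c(session$meals[[meal_index]]$food_entries, list(entry))
  session <- advance_state(session, "item_entry")
  session$last_prompts <- list(
    meal_index = meal_index,
    entry_index = length(session$meals[[meal_index]]$food_entries),
    probes = probes_for(db, food_id),
    linked = linked_options(db, food_id)
  )
  session
}

#' Prompts raised by the most recent add_food
#'
#' @param session A `recall_session`.
#' @return List with `meal_index`, `entry_index`, `probes` (tibble) and
#'   `linked` (tibble), or `NULL` if no food has been added.
#' @export
pending_prompts <- function(session) session$last_prompts

get_entry <- function(session, meal_index, entry_index) {
  if (meal_index < 1 || meal_index > length(session$meals)) {
    stop(sprintf("bad meal index %s", meal_index), call. = FALSE)
  }
  entries <- session$meals[[meal_index]]$food_entries
  if (entry_index < 1 || entry_index > length(entries)) {
    stop(sprintf("bad entry index %s in meal %s", entry_index, meal_index), call. = FALSE)
  }
  entries[[entry_index]]
}

#' Accept a linked-food suggestion
#'
#' Adds the accepted candidate as its own food entry in the same meal,
#' recording the primary selection as its `linked_parent`.
#'
#' @param session A `recall_session`.
#' @param meal_index,entry_index Locate the primary entry whose linked list is
#'   being answered.
#' @param food_id The accepted linked candidate (must be among the primary
#'   item's configured linked options).
#' @param db The `food_db`.
#' @return The updated session (prompts now refer to the new entry).
#' @export
accept_linked <- function(session, meal_index, entry_index, food_id, db) {
  check_not_finalized(session, "accept_linked")
  parent <- get_entry(session, meal_index, entry_index)
  cand <- db$foods$linked_ids[[match(parent$food_id, db$foods$food_id)]]
  if (!food_id %in% cand) {
    stop(sprintf(
      "'%s' is not a linked option of '%s'", food_id, parent$food_id
    ), call. = FALSE)
  }
  add_food(session, meal_index, food_id, db, linked_parent = parent$food_id)
}

#' Answer a probe question on a food entry
#'
#' Probe effects are applied immediately: an annotation effect tags the entry;
#' a substitution effect swaps the entry's `food_id` for the more specific
#' item (the original id is retained in `original_food_id`).
#'
#' @param session A `recall_session`.
#' @param meal_index,entry_index Entry locator.
#' @param probe_id Probe being answered (must be attached to the entry's food).
#' @param option Chosen option label.
#' @param db The `food_db`.
#' @return The updated session.
#' @export
answer_probe <- function(session, meal_index, entry_index, probe_id, option, db) {
  check_not_finalized(session, "answer_probe")
  entry <- get_entry(session, meal_index, entry_index)
  if (!probe_id %in% c(entry$pending_probes, names(entry$probe_answers))) {
    stop(sprintf("probe '%s' is not attached to this entry", probe_id), call. = FALSE)
  }
  p <- db$probes[db$probes$probe_id == probe_id, , drop = FALSE]
  if (nrow(p) == 0) stop(sprintf("unknown probe '%s'", probe_id), call. = FALSE)
  if (!option %in% p$options[[1]]) {
    stop(sprintf("'%s' is not an option of probe '%s'", option, probe_id), call. = FALSE)
  }
  entry$probe_answers[[probe_id]] <- option
  entry$pending_probes <- setdiff(entry$pending_probes, probe_id)
  eff <- p$effects[[1]][[option]]
  if (!is.null(eff)) {
    if (identical(eff$kind, "substitute")) {
      entry$food_id <- eff$value
    } else {
      entry$probe_tags <- union(entry$probe_tags, eff$value)
    }
  }
  session$meals[[meal_index]]$food_entries[[entry_index]] <- entry
  advance_state(session, "detail_entry")
}

#' Record the portion response for a food entry
#'
#' Resolves the response against the item's portion specification via
#' [resolve_portion_weight()] and stores the gram weight on the entry.
#'
#' @param session A `recall_session`.
#' @param meal_index,entry_index Entry locator.
#' @param response A [portion_response()].
#' @param db The `food_db`.
#' @return The updated session.
#' @export
set_portion <- function(session, meal_index, entry_index, response, db) {
  check_not_finalized(session, "set_portion")
  entry <- get_entry(session, meal_index, entry_index)
  spec <- portion_spec_for(db, entry$food_id)
  entry$portion_response <- response
  entry$resolved_weight_g <- resolve_portion_weight(spec, response)
  session$meals[[meal_index]]$food_entries[[entry_index]] <- entry
  advance_state(session, "detail_entry")
}

#' Record a supplement taken on the recalled day
#'
#' @param session A `recall_session`.
#' @param supplement_id Branded supplement id, or `NULL` with
#'   `category_id` set for the generic (median-composition) option.
#' @param category_id Supplement category (required for generic entries).
#' @param generic Use the category's generic composition.
#' @param dose_count Number of doses taken (>= 1).
#' @return The updated session.
#' @export
add_supplement <- function(session, supplement_id = NULL, category_id = NULL,
                           generic = is.null(supplement_id), dose_count = 1) {
  check_not_finalized(session, "add_supplement")
  stopifnot(dose_count >= 1)
  if (generic && is.null(category_id)) {
    stop("generic supplement entries require a category_id", call. = FALSE)
  }
  if (!generic && is.null(supplement_id)) {
    stop("branded supplement entries require a supplement_id", call. = FALSE)
  }
  session$supplements <- c(session$supplements, list(list(
    supplement_id = supplement_id, category_id = category_id,
    generic = generic, dose_count = dose_count
  )))
  session
}

#' Entries blocking finalization
#'
#' @param session A `recall_session`.
#' @return Tibble with one row per unresolved entry: `meal_index`,
#'   `entry_index`, `food_id`, `issue` ("unresolved portion" or
#'   "unanswered probe <id>").
#' @export
session_issues <- function(session) {
  rows <- list()
  for (mi in seq_along(session$meals)) {
    entries <- session$meals[[mi]]$food_entries
    for (ei in seq_along(entries)) {
      e <- entries[[ei]]
      if (is.na(e$resolved_weight_g) || e$resolved_weight_g <= 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          meal_index = mi, entry_index = ei, food_id = e$food_id,
          issue = "unresolved portion"
        )
      }
      for (pid in e$pending_probes) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          meal_index = mi, entry_index = ei, food_id = e$food_id,
          issue = paste0("unanswered probe ", pid)
        )
      }
    }
  }
  if (length(rows) == 0) {
    tibble::tibble(
      meal_index = integer(0), entry_index = integer(0),
      food_id = character(0), issue = character(0)
    )
  } else {
    dplyr::bind_rows(rows)
  }
}

#' Finalize a recall session
#'
#' The closing pass: the respondent has reviewed the selected items and the
#' frequently-forgotten-foods checklist, reported supplement intake, and said
#' whether the day was representative of usual intake. Fails, listing the
#' offending entries, if any food entry still lacks a resolved portion weight
#' or an answered probe. A finalized session is immutable.
#'
#' @param session A `recall_session`.
#' @param supplements Optional list of supplement entries (see
#'   [add_supplement()] for the per-entry fields), appended before closing.
#' @param usual_intake_flag `"usual"`, `"not_usual"` or `"unknown"`.
#' @return The finalized session (state `"finalized"`,
#'   `forgotten_foods_reviewed = TRUE`).
#' @export
finalize_session <- function(session, supplements = NULL, usual_intake_flag = "unknown") {
  stopifnot(inherits(session, "recall_session"))
  if (identical(session$state, "finalized")) {
    stop("session is already finalized", call. = FALSE)
  }
  usual_intake_flag <- match.arg(usual_intake_flag, c("usual", "not_usual", "unknown"))
  if (!is.null(supplements)) {
    for (s in supplements) {
      session <- add_supplement(
        session,
        supplement_id = s$supplement_id %||% NULL,
        category_id = s$category_id %||% NULL,
        generic = s$generic %||% is.null(s$supplement_id),
        dose_count = s$dose_count %||% 1
      )
    }
  }
  issues <- session_issues(session)
  if (nrow(issues) > 0) {
    stop(
      "cannot finalize; unresolved entries:\n  - ",
      paste(sprintf(
        "meal %d entry %d (%s): %s",
        issues$meal_index, issues$entry_index, issues$food_id, issues$issue
      ), collapse = "\n  - "),
      call. = FALSE
    )
  }
  session$forgotten_foods_reviewed <- TRUE
  session$usual_intake_flag <- usual_intake_flag
  session$last_prompts <- NULL
  session$state <- "finalized"
  session
}

#' @export
print.recall_session <- function(x, ...) {
  n_entries <- sum(vapply(x$meals, function(m) length(m$food_entries), integer(1)))
  cat(sprintf(
    "<recall_session> %s @ %s: %d meals, %d entries, %d supplements [%s]\n",
    x$participant_id, x$recall_date, length(x$meals), n_entries,
    length(x$supplements), x$state
  ))
  invisible(x)
}

#' Tidy a recall session into one row per food entry
#'
#' @param x A `recall_session`.
#' @param ... Unused.
#' @return Tibble with meal and entry fields, including resolved weights.
#' @export
tidy.recall_session <- function(x, ...) {
  rows <- list()
  for (mi in seq_along(x$meals)) {
    m <- x$meals[[mi]]
    for (ei in seq_along(m$food_entries)) {
      e <- m$food_entries[[ei]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = x$participant_id, recall_date = x$recall_date,
        meal_index = mi, meal_name = m$meal_name, meal_time = m$time,
        location = m$location, entry_index = ei, food_id = e$food_id,
        original_food_id = e$original_food_id,
        linked_parent = e$linked_parent %||% NA_character_,
        resolved_weight_g = e$resolved_weight_g
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      participant_id = character(0), recall_date = character(0),
      meal_index = integer(0), meal_name = character(0), meal_time = character(0),
      location = character(0), entry_index = integer(0), food_id = character(0),
      original_food_id = character(0), linked_parent = character(0),
      resolved_weight_g = numeric(0)
    ))
  }
  dplyr::bind_rows(rows)
}

#' Write a session to JSON
#'
#' @param session A `recall_session`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recall_session"))
  obj <- unclass(session)
  obj$last_prompts <- NULL
  obj$meals <- lapply(obj$meals, function(m) {
    m$food_entries <- lapply(m$food_entries, function(e) {
      e$portion_response <- if (is.null(e$portion_response)) NULL else unclass(e$portion_response)
      e$probe_tags <- as.list(e$probe_tags)
      e$pending_probes <- as.list(e$pending_probes)
      e
    })
    m
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a session from JSON
#'
#' @param path Path written by [write_session()].
#' @return A `recall_session`.
#' @export
read_session <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  session <- structure(
    list(
      participant_id = obj$participant_id,
      recall_date = obj$recall_date,
      meals = lapply(obj$meals, function(m) {
        list(
          meal_name = m$meal_name, time = m$time, location = m$location,
          food_entries = lapply(m$food_entries, function(e) {
            pr <- e$portion_response
            if (!is.null(pr)) {
              pr <- portion_response(
                kind = pr$kind,
                image_index = pr$image_index %||% NULL,
                relation = pr$relation %||% NULL,
                unit_count = pr$unit_count %||% NULL
              )
            }
            list(
              food_id = e$food_id,
              original_food_id = e$original_food_id,
              probe_answers = lapply(e$probe_answers, identity),
              probe_tags = as.character(unlist(e$probe_tags)),
              pending_probes = as.character(unlist(e$pending_probes)),
              portion_response = pr,
              resolved_weight_g = e$resolved_weight_g %||% NA_real_,
              linked_parent = e$linked_parent %||% NULL
            )
          })
        )
      }),
      supplements = lapply(obj$supplements, function(s) {
        list(
          supplement_id = s$supplement_id %||% NULL,
          category_id = s$category_id %||% NULL,
          generic = isTRUE(s$generic),
          dose_count = s$dose_count
        )
      }),
      forgotten_foods_reviewed = isTRUE(obj$forgotten_foods_reviewed),
      usual_intake_flag = obj$usual_intake_flag,
      state = obj$state,
      last_prompts = NULL
    ),
    class = "recall_session"
  )
  session
}

#' Run an answer script against a database
#'
#' Drives a whole session non-interactively from an ordered list of actions,
#' the headless equivalent of a respondent clicking through the passes. Each
#' action is a list with an `action` field (`add_meal`, `add_food`,
#' `answer_probe`, `accept_linked`, `set_portion`, `add_supplement`,
#' `finalize`) and that operation's arguments; entry locators are
#' `meal_index`/`entry_index` in the current time-sorted meal order.
#'
#' @param db A `food_db`.
#' @param script A list of actions, or path to a JSON file holding
#'   `participant_id`, `recall_date` and `actions`.
#' @param participant_id,recall_date Used when `script` is a bare action list.
#' @return The resulting `recall_session` (finalized if the script says so).
#' @export
run_answer_script <- function(db, script, participant_id = NULL, recall_date = NULL) {
  if (is.character(script)) {
    obj <- jsonlite::read_json(script, simplifyVector = FALSE)
    participant_id <- obj$participant_id
    recall_date <- obj$recall_date
    actions <- obj$actions
  } else {
    actions <- script
  }
  stopifnot(!is.null(participant_id), !is.null(recall_date))
  s <- start_session(participant_id, recall_date)
  for (a in actions) {
    s <- switch(a$action,
      add_meal = add_meal(s, a$meal_name, a$time, a$location %||% "unknown"),
      add_food = add_food(s, a$meal_index, a$food_id, db),
      answer_probe = answer_probe(s, a$meal_index, a$entry_index, a$probe_id, a$option, db),
      accept_linked = accept_linked(s, a$meal_index, a$entry_index, a$food_id, db),
      set_portion = set_portion(
        s, a$meal_index, a$entry_index,
        portion_response(
          kind = a$kind,
          image_index = a$image_index %||% NULL,
          relation = a$relation %||% NULL,
          unit_count = a$unit_count %||% NULL
        ), db
      ),
      add_supplement = add_supplement(
        s,
        supplement_id = a$supplement_id %||% NULL,
        category_id = a$category_id %||% NULL,
        generic = a$generic %||% is.null(a$supplement_id),
        dose_count = a$dose_count %||% 1
      ),
      finalize = finalize_session(s, usual_intake_flag = a$usual_intake_flag %||% "unknown"),
      stop(sprintf("unknown action '%s'", a$action), call. = FALSE)
    )
  }
  s
}
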