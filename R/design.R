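#' Construct the item set for a 2 x 3 stereotype design
#'
#' Builds the occupation/item/filler inventory of a visual-world experiment
#' crossing visually derived occupation stereotypes (female vs. male) with
#' verbally conveyed action stereotypes (female vs. male vs. neutral). Each
#' experimental item is a display built around one occupation and carries
#' three action variants; fillers are separate trials with a yes/no
#' engagement-check question.
#'
#' @param n_occupations Even number of occupations; half are labelled
#'   female-stereotypical, half male-stereotypical.
#' @param displays_per_occupation Number of distinct displays (items) built
#'   per occupation.
#' @param n_fillers Number of filler trials.
#' @return An object of class `item_set`: a list with data.tables
#'   `occupations` (occupation_id, occupation_stereotype), `items`
#'   (item_id, occupation_id, occupation_stereotype, and the three action
#'   variants), and `fillers` (filler_id, question_key).
#' @examples
#' is <- build_item_set(14, 3, 28)
#' nrow(is$items)   # 42
#' @export
build_item_set <- function(n_occupations = 14, displays_per_occupation = 3,
                           n_fillers = 28) {
  if (!is.numeric(n_occupations) || n_occupations < 2)
    stop("n_occupations must be a number >= 2")
  if (n_occupations %% 2 != 0)
    stop("n_occupations must be even so occupation stereotypes balance")
  if (displays_per_occupation < 1) stop("displays_per_occupation must be >= 1")
  if (n_fillers < 1) stop("n_fillers must be >= 1")

  # alternate stereotype across occupation ids: keeps any contiguous block of
  # occupations balanced and makes the agent-gender alternation rule simple
  occupations <- data.table::data.table(
    occupation_id = seq_len(n_occupations),
    occupation_stereotype = rep(c("female", "male"),
                                length.out = n_occupations)
  )
  items <- data.table::data.table(
    item_id = seq_len(n_occupations * displays_per_occupation),
    occupation_id = rep(occupations$occupation_id,
                        each = displays_per_occupation)
  )
  items <- merge(items, occupations, by = "occupation_id", sort = TRUE)
  data.table::setcolorder(items, c("item_id", "occupation_id",
                                   "occupation_stereotype"))
  data.table::setkey(items, item_id)
  for (v in c("female", "male", "neutral"))
    items[, paste0("action_", v) := paste0("act_", v, "_", item_id)]

  fillers <- data.table::data.table(
    filler_id = max(items$item_id) + seq_len(n_fillers),
    question_key = rep(c("yes", "no"), length.out = n_fillers)
  )
  structure(list(occupations = occupations, items = items, fillers = fillers),
            class = "item_set")
}

#' @export
print.item_set <- function(x, ...) {
  cat(sprintf("item_set: %d occupations, %d items, %d fillers\n",
              nrow(x$occupations), nrow(x$items), nrow(x$fillers)))
  invisible(x)
}

# the fixed enumeration of the six design cells
design_cells <- function() {
  data.table::data.table(
    cell = 1:6,
    occupation_stereotype = rep(c("female", "male"), each = 3),
    action_stereotype = rep(c("female", "male", "neutral"), times = 2)
  )
}

#' Latin-square assignment of items to design cells across six lists
#'
#' Rotates every item through the six (occupation x action) cells across six
#' presentation lists by cyclic rotation, so that each item occurs exactly
#' once per list and appears in every cell exactly once over the six lists,
#' with each cell covering items/6 items within a list.
#'
#' The agent (the character the sentence eventually names) is the one
#' matching the display's occupation stereotype: the female character in a
#' female-stereotypical occupation display, the male character in a
#' male-stereotypical one. Occupation conditions are balanced within every
#' list, so each list presents equally many female- and male-agent trials;
#' the post-noun referential gaze shift therefore also separates the two
#' occupation conditions.
#'
#' @param item_set An [build_item_set()] result.
#' @return List of six data.tables (classes `presentation_list`), one per
#'   list, each with one row per experimental item: list_id, item_id,
#'   occupation_id, occupation_stereotype, action_stereotype, agent_gender,
#'   cell.
#' @export
latin_square_lists <- function(item_set) {
  stopifnot(inherits(item_set, "item_set"))
  items <- item_set$items
  if (nrow(items) %% 6 != 0)
    stop("number of items (", nrow(items), ") must be divisible by 6")
  cells <- design_cells()
  lists <- lapply(1:6, function(l) {
    dt <- data.table::copy(items[, .(item_id, occupation_id)])
    dt[, list_id := l]
    dt[, cell := ((item_id - 1L + l - 1L) %% 6L) + 1L]
    dt <- merge(dt, cells, by = "cell", sort = FALSE)
    # the sentence names the character matching the display's occupation
    # stereotype (florist_female in a female-stereotypical display,
    # soldier_male in a male-stereotypical one); occupation conditions are
    # balanced within a list, so each list has equally many female- and
    # male-agent trials
    dt[, agent_gender := occupation_stereotype]
    data.table::setkey(dt, item_id)
    data.table::setcolorder(dt, c("list_id", "item_id", "occupation_id",
                                  "occupation_stereotype",
                                  "action_stereotype", "agent_gender",
                                  "cell"))
    class(dt) <- c("presentation_list", class(dt))
    dt
  })
  lists
}

# Uniform draw of a filler/experimental sequence pattern with a maximum
# experimental run length, by dynamic programming over the gaps that follow
# each filler.  Returns gap sizes g[1..n_fillers] (g[i] experimental trials
# right after filler i); the sequence starts with a filler, so every
# experimental run sits in one gap and is <= max_run by construction.
sample_run_pattern <- function(n_exp, n_fillers, max_run = 2L, rng = NULL) {
  # counts[i, r+1] = number of ways gaps i..n_fillers sum to r
  counts <- matrix(0, nrow = n_fillers + 1L, ncol = n_exp + 1L)
  counts[n_fillers + 1L, 1L] <- 1
  for (i in n_fillers:1) {
    for (r in 0:n_exp) {
      tot <- 0
      for (g in 0:min(max_run, r))
        tot <- tot + counts[i + 1L, r - g + 1L]
      counts[i, r + 1L] <- tot
    }
  }
  if (counts[1L, n_exp + 1L] == 0)
    stop(sprintf(paste0("randomization constraints unsatisfiable: %d ",
                        "experimental trials need at least %d fillers ",
                        "(have %d)"),
                 n_exp, ceiling(n_exp / max_run), n_fillers))
  g <- integer(n_fillers)
  r <- n_exp
  for (i in seq_len(n_fillers)) {
    gs <- 0:min(max_run, r)
    w <- counts[i + 1L, r - gs + 1L]
    g[i] <- if (length(gs) == 1L) gs else sample(gs, 1L, prob = w)
    r <- r - g[i]
  }
  g
}

#' Pseudo-randomize trial presentation
#'
#' Orders the experimental trials of one presentation list together with its
#' fillers so that (i) the first trial is a filler and (ii) no more than
#' `max_run` experimental trials are consecutive. The order is uniform over
#' all orders satisfying the constraints: the filler/experimental run pattern
#' is drawn uniformly by dynamic programming, then trial identities are
#' assigned by uniform permutation within type (every valid pattern carries
#' equally many full orders).
#'
#' @param plist One element of [latin_square_lists()].
#' @param fillers The `fillers` table of the item set.
#' @param seed Integer seed; the order is reproducible given the seed.
#' @param max_run Maximum allowed run of consecutive experimental trials.
#' @return data.table with one row per presented trial: position, trial_type
#'   ("experimental"/"filler"), trial columns from `plist` (NA for fillers),
#'   filler_id (NA for experimental trials).
#' @export
randomize_presentation <- function(plist, fillers, seed, max_run = 2L) {
  n_exp <- nrow(plist)
  n_fil <- nrow(fillers)
  if (n_fil < 1 && n_exp > 0)
    stop("randomization constraints unsatisfiable: need at least 1 filler")
  ord <- withr_seed(seed, {
    if (n_exp == 0) {
      rep("F", n_fil)
    } else {
      g <- sample_run_pattern(n_exp, n_fil, max_run = max_run)
      unlist(lapply(seq_len(n_fil), function(i) c("F", rep("E", g[i]))))
    }
  })
  withr_seed(seed + 1L, {
    exp_ids <- plist$item_id[sample.int(n_exp)]
    fil_ids <- fillers$filler_id[sample.int(n_fil)]
  })
  out <- data.table::data.table(position = seq_along(ord), trial_type =
                                  ifelse(ord == "E", "experimental", "filler"))
  out[trial_type == "experimental", item_id := exp_ids]
  out[trial_type == "filler", filler_id := fil_ids]
  out <- merge(out, plist, by = "item_id", all.x = TRUE, sort = FALSE)
  data.table::setorder(out, position)
  data.table::setcolorder(out, c("position", "trial_type", "item_id"))
  out
}

# evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Serialize a full six-list design to one trial-per-row table
#'
#' @param lists Result of [latin_square_lists()].
#' @param item_set The item set the lists were built from.
#' @param seed Base seed; list `l` is randomized with `seed + l`.
#' @return data.table of all six lists' ordered trials.
#' @export
design_table <- function(lists, item_set, seed = 1L) {
  data.table::rbindlist(lapply(lists, function(pl) {
    out <- randomize_presentation(pl, item_set$fillers,
                                  seed = seed + pl$list_id[1])
    out[, list_id := pl$list_id[1]]
    out
  }), fill = TRUE)
}
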