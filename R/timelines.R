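new_timeline <- function(events, design, total_duration_ms, tr_ms, seed) {
  stopifnot(all(c("onset_ms", "duration_ms", "label", "numerosity",
                  "display_ref", "attention_flag") %in% names(events)))
  if (is.unsorted(events$onset_ms, strictly = TRUE)) {
    abort("Event onsets must be strictly increasing.")
  }
  if (any(head(events$onset_ms + events$duration_ms, -1) > tail(events$onset_ms, -1))) {
    abort("Events must not overlap in time.")
  }
  if (nrow(events) && total_duration_ms <
      max(events$onset_ms + events$duration_ms)) {
    abort("`total_duration_ms` must cover the last event.")
  }
  structure(events,
            class = c("nt_timeline", class(tibble())),
            design = design, total_duration_ms = total_duration_ms,
            tr_ms = tr_ms, seed = seed)
}

timeline_design <- function(x) attr(x, "design")
timeline_duration_ms <- function(x) attr(x, "total_duration_ms")
timeline_tr_ms <- function(x) attr(x, "tr_ms")

#' Build the numerosity-sweep localizer timeline
#'
#' The localizer presents 1-7 dots in ascending order, then a long baseline
#' of 20 dots, the descending sweep, and a second baseline; the whole
#' sequence repeats `sweep_repetitions` times per run. Each numerosity is
#' shown `reps_per_numerosity` times (new random dot pattern every
#' `cycle_ms`, shown for `presentation_ms`), so an epoch spans
#' `reps_per_numerosity * cycle_ms` (3900 ms at the defaults). About
#' `oddball_rate` of presentations are white-dot attention oddballs.
#'
#' @param presentation_ms,cycle_ms Dot-pattern duration and onset asynchrony.
#' @param reps_per_numerosity Patterns per numerosity epoch.
#' @param sweep Numerosities of the ascending sweep.
#' @param baseline_numerosity,baseline_epochs The high-numerosity baseline
#'   and how many epochs its "long period" spans.
#' @param sweep_repetitions Ascending-baseline-descending-baseline cycles
#'   per run.
#' @param oddball_rate Probability a presentation uses white dots.
#' @param tr_ms Repetition time, ms.
#' @param seed Integer seed (oddball placement).
#' @return A timeline tibble (`nt_timeline`) with one row per presentation.
#' @export
build_localizer_timeline <- function(presentation_ms = 300, cycle_ms = 650,
                                     reps_per_numerosity = 6, sweep = 1:7,
                                     baseline_numerosity = 20,
                                     baseline_epochs = 6,
                                     sweep_repetitions = 4,
                                     oddball_rate = 0.10,
                                     tr_ms = 1500, seed = 1) {
  if (presentation_ms > cycle_ms) {
    abort("`presentation_ms` cannot exceed `cycle_ms`.")
  }
  assert_scalar_number(oddball_rate, "oddball_rate", 0, 1)
  epoch_n <- c(sweep, rep(baseline_numerosity, baseline_epochs),
               rev(sweep), rep(baseline_numerosity, baseline_epochs))
  epoch_n <- rep(epoch_n, sweep_repetitions)
  epoch_ms <- reps_per_numerosity * cycle_ms

  n_events <- length(epoch_n) * reps_per_numerosity
  onset <- rep(seq_along(epoch_n) - 1L, each = reps_per_numerosity) * epoch_ms +
    rep(seq_len(reps_per_numerosity) - 1L, times = length(epoch_n)) * cycle_ms
  numer <- rep(epoch_n, each = reps_per_numerosity)
  odd <- with_seed(seed, runif(n_events) < oddball_rate)

  events <- tibble(
    onset_ms = as.integer(onset),
    duration_ms = as.integer(presentation_ms),
    label = "dots",
    numerosity = as.integer(numer),
    display_ref = sprintf("loc_n%02d_e%04d", numer, seq_len(n_events)),
    attention_flag = odd
  )
  new_timeline(events, "localizer_sweep",
               total_duration_ms = length(epoch_n) * epoch_ms,
               tr_ms = tr_ms, seed = seed)
}

block_categories <- function() {
  c("nat_low", "nat_high", "scenery", "dot_low", "dot_20", "dot_high")
}

natural_categories <- function() c("nat_low", "nat_high", "scenery")

# Map a block category to the manifest pool it draws from.
category_pool <- function(manifest, category) {
  pools <- list(
    nat_low = c("nat_one", "nat_two", "nat_three"),
    nat_high = "nat_high", scenery = "scenery",
    dot_low = "dot_low", dot_20 = "dot_20", dot_high = "dot_high"
  )
  manifest[manifest$category %in% pools[[category]], , drop = FALSE]
}

#' Build the six-category block-design timeline
#'
#' Twelve 15-s stimulus blocks (each of the six categories twice, in
#' seeded-random order), each followed by 15 s of rest. A block shows 30
#' items drawn without replacement from the category's pool, each for
#' 300 ms with 200 ms of gray between items.
#'
#' @param manifest A [build_pool_manifest()] tibble supplying the pools and
#'   their object-count annotations.
#' @param repeats Blocks per category.
#' @param events_per_block Items shown per block.
#' @param on_ms,off_ms Item duration and inter-item gap.
#' @param rest_ms Rest period after each block.
#' @param tr_ms Repetition time, ms.
#' @param seed Integer seed (block order and pool draws).
#' @return A timeline tibble (`nt_timeline`), one row per item presentation;
#'   each event carries its item's object count (`NA` for scenery).
#' @export
build_block_timeline <- function(manifest, repeats = 2, events_per_block = 30,
                                 on_ms = 300, off_ms = 200, rest_ms = 15000,
                                 tr_ms = 1500, seed = 1) {
  categories <- block_categories()
  soa <- on_ms + off_ms
  block_ms <- events_per_block * soa
  for (cat in categories) {
    if (nrow(category_pool(manifest, cat)) < events_per_block) {
      abort(sprintf("Pool for category '%s' has fewer than %d items.",
                    cat, events_per_block))
    }
  }
  with_seed(seed, {
    order <- sample(rep(categories, repeats))
    blocks <- purrr::imap(order, function(cat, k) {
      pool <- category_pool(manifest, cat)
      draw <- pool[sample.int(nrow(pool), events_per_block), , drop = FALSE]
      start <- (k - 1L) * (block_ms + rest_ms)
      tibble(
        onset_ms = as.integer(start + (seq_len(events_per_block) - 1L) * soa),
        duration_ms = as.integer(on_ms),
        label = cat,
        numerosity = draw$n_objects,
        display_ref = draw$item_id,
        attention_flag = FALSE
      )
    })
    events <- dplyr::bind_rows(blocks)
    new_timeline(events, "category_block",
                 total_duration_ms = length(order) * (block_ms + rest_ms),
                 tr_ms = tr_ms, seed = seed)
  })
}

#' Write a timeline as a BIDS-style events TSV
#'
#' Columns `onset` and `duration` are in seconds per the BIDS events
#' convention; `label`, `numerosity`, `display_ref` and `attention_flag`
#' ride along as extra columns. A JSON sidecar (same path, `.json`) records
#' the design, total duration, TR and seed so the timeline round-trips.
#'
#' @param timeline An `nt_timeline`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(timeline, path) {
  stopifnot(inherits(timeline, "nt_timeline"))
  out <- tibble(
    onset = ms_to_s(timeline$onset_ms),
    duration = ms_to_s(timeline$duration_ms),
    label = timeline$label,
    numerosity = timeline$numerosity,
    display_ref = timeline$display_ref,
    attention_flag = timeline$attention_flag
  )
  readr::write_tsv(out, path)
  sidecar <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(design = timeline_design(timeline),
         total_duration_ms = timeline_duration_ms(timeline),
         tr_ms = timeline_tr_ms(timeline), seed = attr(timeline, "seed")),
    sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' Read a timeline from a BIDS-style events TSV
#'
#' @param path TSV path written by [write_events_tsv()] (its JSON sidecar is
#'   read when present).
#' @return An `nt_timeline`.
#' @export
read_events_tsv <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  events <- tibble(
    onset_ms = s_to_ms(ev$onset),
    duration_ms = s_to_ms(ev$duration),
    label = as.character(ev$label),
    numerosity = as.integer(ev$numerosity),
    display_ref = as.character(ev$display_ref),
    attention_flag = as.logical(ev$attention_flag)
  )
  new_timeline(events,
               design = meta$design %||% NA_character_,
               total_duration_ms = meta$total_duration_ms %||%
                 max(events$onset_ms + events$duration_ms),
               tr_ms = meta$tr_ms %||% 1500,
               seed = meta$seed %||% NA_integer_)
}
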