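# Stable-isotope sample QC and regurgitate diet composition tables.
# Diet percentages are printed half-up to 1 decimal, matching the convention
# of published composition tables.

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Read an isotope sample table
#'
#' Expects columns `individual_id`, `tissue` (blood/feather), `stage`
#' (incubation/chick_rearing/moult), `d13C`, `d15N`, `cn_ratio`.
#'
#' @param path Path to a CSV file.
#' @return Data.frame of isotope samples.
#' @export
read_isotope_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "tissue", "stage", "d13C", "d15N", "cn_ratio")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_isotope_csv: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Quality-control isotope samples
#'
#' Blood samples with a C:N mass ratio at or above 3.5 indicate lipid
#' enrichment that biases d13C and are flagged for lipid correction; all
#' other samples pass (the rule applies to blood only, since feathers are
#' cleaned of surface lipids before analysis).
#'
#' @param samples Isotope sample data.frame (see [read_isotope_csv()]).
#' @param cn_max Flagging threshold for blood C:N.
#' @return List with data.frames `passed` and `flagged`.
#' @export
qc_isotopes <- function(samples, cn_max = 3.5) {
  flag <- samples$tissue == "blood" & samples$cn_ratio >= cn_max
  list(passed = samples[!flag, , drop = FALSE],
       flagged = samples[flag, , drop = FALSE])
}

#' Read a long-format diet table
#'
#' Expects columns `sample_id`, `individual_id`, `stage`, `species`,
#' `prey_group`, `count` (items of that species in that sample).
#'
#' @param path Path to a CSV file.
#' @return Data.frame of diet records.
#' @export
read_diet_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "individual_id", "species", "prey_group", "count")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_diet_csv: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Diet composition table from aggregated counts
#'
#' Given per-species item totals and the number of samples containing each
#' species, computes the proportion of all prey items and the proportion of
#' samples associated with each species, both half-up rounded to 1 decimal.
#'
#' @param counts Data.frame with `species`, `prey_group`, `n_items`,
#'   `n_samples`.
#' @param total_samples Total number of samples collected (the denominator
#'   for the per-sample percentages).
#' @return Data.frame: `species`, `prey_group`, `n_items`, `pct_items`,
#'   `n_samples`, `pct_samples`.
#' @export
diet_composition_from_counts <- function(counts, total_samples) {
  stopifnot(all(c("species", "n_items", "n_samples") %in% names(counts)))
  counts <- counts[counts$n_items > 0, , drop = FALSE]
  if (nrow(counts) == 0) stop("diet_composition_from_counts: no prey items")
  total_items <- sum(counts$n_items)
  out <- data.frame(
    species = counts$species,
    prey_group = if ("prey_group" %in% names(counts)) counts$prey_group
                 else NA_character_,
    n_items = counts$n_items,
    pct_items = round_half_up(100 * counts$n_items / total_items, 1),
    n_samples = counts$n_samples,
    pct_samples = round_half_up(100 * counts$n_samples / total_samples, 1),
    stringsAsFactors = FALSE)
  attr(out, "total_items") <- total_items
  attr(out, "total_samples") <- total_samples
  out
}

#' Diet composition table from sample-level records
#'
#' Aggregates long-format diet records (one row per sample x species) into
#' per-species item totals and sample occurrence, then computes the
#' composition percentages. Species never observed (zero count everywhere)
#' are excluded.
#'
#' @param samples Long-format diet data.frame (see [read_diet_csv()]).
#' @return As [diet_composition_from_counts()].
#' @export
diet_composition <- function(samples) {
  if (nrow(samples) == 0) stop("diet_composition: need at least 1 sample")
  total_samples <- length(unique(samples$sample_id))
  pos <- samples[samples$count > 0, , drop = FALSE]
  n_items <- tapply(pos$count, pos$species, sum)
  n_samp <- tapply(pos$sample_id, pos$species,
                   function(s) length(unique(s)))
  grp <- tapply(pos$prey_group, pos$species, `[`, 1)
  sp <- names(n_items)
  diet_composition_from_counts(
    data.frame(species = sp, prey_group = as.character(grp[sp]),
               n_items = as.integer(n_items[sp]),
               n_samples = as.integer(n_samp[sp]),
               stringsAsFactors = FALSE),
    total_samples = total_samples)
}

#' Dominant-prey consistency across repeat samples
#'
#' For each individual with at least two samples, determines the dominant
#' species of every sample (largest item count; ties broken alphabetically
#' and flagged) and reports whether the dominant prey stayed the same.
#'
#' @param samples Long-format diet data.frame.
#' @return Data.frame: `individual_id`, `n_samples`, `dominant` (comma-
#'   separated per-sample winners), `consistent`, `tie_flagged`.
#' @export
dominant_prey_consistency <- function(samples) {
  dominant_of_sample <- function(s) {
    tot <- tapply(s$count, s$species, sum)
    tot <- tot[tot > 0]
    win <- sort(names(tot)[tot == max(tot)])
    list(species = win[1], tie = length(win) > 1)
  }
  rows <- lapply(split(samples, samples$individual_id), function(d) {
    per <- lapply(split(d, d$sample_id), dominant_of_sample)
    if (length(per) < 2) return(NULL)
    doms <- vapply(per, `[[`, "", "species")
    data.frame(individual_id = d$individual_id[1],
               n_samples = length(per),
               dominant = paste(doms, collapse = ","),
               consistent = length(unique(doms)) == 1,
               tie_flagged = any(vapply(per, `[[`, TRUE, "tie")),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(individual_id = character(), n_samples = integer(),
                      dominant = character(), consistent = logical(),
                      tie_flagged = logical()))
  }
  rownames(res) <- NULL
  res
}

#' The shipped Kerguelen shag diet composition counts
#'
#' Aggregate regurgitate diet table for Kerguelen shags at a subantarctic
#' colony: per prey species, the total number of items identified across 26
#' regurgitate samples and the number of samples containing the species.
#'
#' @return List: `counts` (data.frame) and `total_samples` (26).
#' @export
shag_diet_counts <- function() {
  path <- system.file("extdata", "shag_diet_counts.csv",
                      package = "foragespec", mustWork = TRUE)
  list(counts = utils::read.csv(path, stringsAsFactors = FALSE),
       total_samples = 26L)
}
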