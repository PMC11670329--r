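#' Aggregate a 214-day daily series to 53 period means
#'
#' Periods 1-52 are means of consecutive 4-day windows (days 1-4, 5-8, ...,
#' 205-208); period 53 is the mean of the remaining 6 days (209-214). The
#' final period absorbs the two leftover days so that all 214 days
#' contribute, giving the 214:53 dimension reduction.
#'
#' @param daily Numeric vector of length 214, or a matrix with 214 columns
#'   (one row per record/environment).
#' @return A numeric vector of length 53, or a matrix with 53 columns.
#' @export
aggregate_weather <- function(daily) {
  if (is.matrix(daily)) {
    abort_if(ncol(daily) != N_DAYS,
             "daily weather must have ", N_DAYS, " columns, got ", ncol(daily))
    out <- matrix(0, nrow(daily), N_PERIODS)
    for (p in seq_len(N_PERIODS)) {
      out[, p] <- rowMeans(daily[, period_days(p), drop = FALSE])
    }
    return(out)
  }
  abort_if(length(daily) != N_DAYS,
           "daily weather must have length ", N_DAYS, ", got ", length(daily))
  vapply(seq_len(N_PERIODS), function(p) mean(daily[period_days(p)]), numeric(1))
}

period_days <- function(p) {
  if (p < N_PERIODS) (4L * (p - 1L) + 1L):(4L * p) else 209:214
}

#' Fit z-score normalisation statistics
#'
#' Computes per-column mean and population (divisor-n) standard deviation
#' over a declared reference row set, by default the training rows, so that
#' no information from validation/test rows leaks into the scaling.
#' Zero-variance columns are flagged; [apply_normalization()] maps them to 0.
#'
#' @param x Numeric matrix (rows = records, columns = aggregated weather and
#'   optionally soil variables).
#' @param reference Logical mask (or integer indices) selecting >= 2 rows.
#' @return An object of class `norm_stats`: list with `mean`, `sd`,
#'   `zero_variance` (logical), `columns`.
#' @export
fit_normalization <- function(x, reference = seq_len(nrow(x))) {
  abort_if(!is.matrix(x) || !is.numeric(x), "x must be a numeric matrix")
  ref <- x[reference, , drop = FALSE]
  abort_if(nrow(ref) < 2L, "reference set must contain at least 2 rows")
  mu <- colMeans(ref)
  sdev <- sqrt(colMeans(sweep(ref, 2L, mu)^2))
  structure(list(mean = mu, sd = sdev, zero_variance = sdev == 0,
                 columns = colnames(x)),
            class = "norm_stats")
}

#' Apply fitted z-score normalisation
#'
#' Standardises columns as `(w - mean) / sd` with the statistics from
#' [fit_normalization()]; columns flagged as zero-variance map to 0.
#'
#' @param x Numeric matrix with columns aligned to the fitted statistics.
#' @param stats A `norm_stats` object.
#' @return Matrix of standardised values, same shape as `x`.
#' @export
apply_normalization <- function(x, stats) {
  abort_if(!inherits(stats, "norm_stats"), "stats must come from fit_normalization")
  abort_if(ncol(x) != length(stats$mean),
           "column mismatch: matrix has ", ncol(x), " columns, stats have ",
           length(stats$mean))
  if (!is.null(colnames(x)) && !is.null(stats$columns)) {
    abort_if(!identical(colnames(x), stats$columns),
             "column names do not match the fitted statistics")
  }
  denom <- ifelse(stats$zero_variance, 1, stats$sd)
  out <- sweep(sweep(x, 2L, stats$mean), 2L, denom, "/")
  if (any(stats$zero_variance)) out[, stats$zero_variance] <- 0
  out
}

#' Build the ordered category registry for one-hot encoding
#'
#' @param records Trial records `data.frame` (typically the training rows).
#' @return List with sorted unique `year`, `location`, `genotype` levels.
#' @export
build_category_registry <- function(records) {
  list(year = sort(unique(records$year)),
       location = sort(unique(records$location_id)),
       genotype = sort(unique(records$genotype_id)))
}

#' One-hot encode year, location and genotype
#'
#' One binary column per registered category, in registry order. Categories
#' absent from the registry (e.g. a new genotype at prediction time) encode
#' as all zeros within their block; other blocks are unaffected.
#'
#' @param records Trial records `data.frame`.
#' @param registry Output of [build_category_registry()].
#' @return Binary matrix with `length(year) + length(location) +
#'   length(genotype)` columns and a `"blocks"` attribute giving the column
#'   indices of the `year`, `location` and `genotype` blocks.
#' @export
one_hot_encode <- function(records, registry) {
  n <- nrow(records)
  blocks <- list(
    year = as.character(registry$year),
    location = registry$location,
    genotype = registry$genotype
  )
  values <- list(
    year = as.character(records$year),
    location = records$location_id,
    genotype = records$genotype_id
  )
  sizes <- vapply(blocks, length, integer(1))
  out <- matrix(0, n, sum(sizes))
  cn <- character(sum(sizes))
  idx <- list()
  offset <- 0L
  for (b in names(blocks)) {
    cols <- offset + seq_len(sizes[[b]])
    idx[[b]] <- cols
    cn[cols] <- paste0(b, "_", blocks[[b]])
    pos <- match(values[[b]], blocks[[b]])
    hit <- !is.na(pos)
    out[cbind(which(hit), offset + pos[hit])] <- 1
    offset <- offset + sizes[[b]]
  }
  colnames(out) <- cn
  attr(out, "blocks") <- idx
  out
}

#' Split records by unique genotype-location combination
#'
#' Unique genotype-location combination keys are shuffled under the seed and
#' partitioned 60/40; the 40% is split evenly into validation and test. Any
#' genotype then absent from the training rows is repaired: its first
#' occurrence in dataset row order (validation searched before test) moves,
#' as a whole combination, to the training set. The resulting masks are
#' pairwise disjoint, cover all rows, share no combination across splits,
#' and every genotype appears in the training rows.
#'
#' @param records Trial records `data.frame` (non-empty).
#' @param fractions Length-3 numeric summing to 1 (train, validation, test).
#' @param seed Integer seed for the combination shuffle.
#' @return Object of class `gem_split`: list with logical masks `train`,
#'   `validation`, `test`, the per-row `combination` key, `seed` and a count
#'   `n_repaired` of combinations moved by the coverage repair.
#' @export
split_by_combination <- function(records, fractions = c(0.60, 0.20, 0.20),
                                 seed = 1L) {
  abort_if(nrow(records) == 0L, "records must be non-empty")
  abort_if(length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9,
           "fractions must be three numbers summing to 1")
  combo <- paste(records$genotype_id, records$location_id, sep = "::")
  u <- unique(combo)
  n <- length(u)
  set.seed(as.integer(seed))
  shuffled <- sample(u)
  n_tr <- round(n * fractions[1])
  n_val <- round(n * fractions[2])
  n_te <- n - n_tr - n_val
  abort_if(n_te < 0, "fractions leave no room for a test split")
  assign <- setNames(rep.int(c("train", "validation", "test"),
                             c(n_tr, n_val, n_te)), shuffled)
  row_split <- assign[combo]

  # coverage repair: every genotype must be present in train
  n_repaired <- 0L
  missing <- setdiff(unique(records$genotype_id),
                     unique(records$genotype_id[row_split == "train"]))
  for (g in missing) {
    rows_g <- which(records$genotype_id == g)
    cand <- rows_g[row_split[rows_g] == "validation"]
    if (length(cand) == 0L) cand <- rows_g[row_split[rows_g] == "test"]
    abort_if(length(cand) == 0L, "genotype ", g, " occurs nowhere in records")
    moved <- combo[cand[1L]]
    row_split[combo == moved] <- "train"
    n_repaired <- n_repaired + 1L
  }

  out <- structure(list(
    train = unname(row_split == "train"),
    validation = unname(row_split == "validation"),
    test = unname(row_split == "test"),
    combination = combo,
    seed = as.integer(seed),
    n_repaired = n_repaired
  ), class = "gem_split")
  validate_split(out, records)
  out
}

validate_split <- function(split, records) {
  m <- cbind(split$train, split$validation, split$test)
  abort_if(any(rowSums(m) != 1L), "split masks must partition the rows")
  for (a in 1:2) for (b in (a + 1):3) {
    abort_if(length(intersect(unique(split$combination[m[, a]]),
                              unique(split$combination[m[, b]]))) > 0L,
             "genotype-location combinations overlap across splits")
  }
  abort_if(!all(unique(records$genotype_id) %in%
                  records$genotype_id[split$train]),
           "some genotypes are absent from the training split")
  invisible(split)
}

#' Write / read split masks as a sidecar CSV
#'
#' @param split A `gem_split` object.
#' @param path CSV path; columns `row`, `split` (`train|val|test`),
#'   `combination`.
#' @return `write_split_csv` returns `path` invisibly; `read_split_csv`
#'   returns a `gem_split`.
#' @export
write_split_csv <- function(split, path) {
  lab <- ifelse(split$train, "train", ifelse(split$validation, "val", "test"))
  data.table::fwrite(data.frame(row = seq_along(lab), split = lab,
                                combination = split$combination,
                                seed = split$seed), path)
  invisible(path)
}

#' @rdname write_split_csv
#' @export
read_split_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  structure(list(train = df$split == "train",
                 validation = df$split == "val",
                 test = df$split == "test",
                 combination = df$combination,
                 seed = df$seed[1L],
                 n_repaired = NA_integer_),
            class = "gem_split")
}

#' Merge a state-level soil table into trial records
#'
#' All records sharing a state receive identical soil values; the 66 soil
#' columns (11 properties x 6 depths) are appended and later standardised
#' alongside the aggregated weather.
#'
#' @param records Trial records `data.frame` with a `state` column.
#' @param soil_table `data.frame` keyed by `state` with one numeric column
#'   per soil property-depth combination.
#' @return `records` with the soil columns appended.
#' @export
merge_soil <- function(records, soil_table) {
  abort_if(!"state" %in% names(soil_table), "soil_table needs a 'state' column")
  missing <- setdiff(unique(records$state), soil_table$state)
  abort_if(length(missing) > 0L,
           "states missing from soil table: ", paste(missing, collapse = ", "))
  soil_cols <- setdiff(names(soil_table), "state")
  abort_if(length(soil_cols) == 0L, "soil_table has no soil columns")
  pos <- match(records$state, soil_table$state)
  cbind(records, soil_table[pos, soil_cols, drop = FALSE],
        row.names = NULL)
}

#' Example soil table at the study's schema
#'
#' Builds a synthetic state-keyed soil table with the standard 11 soil
#' properties (bdod, cec, cfvo, clay, nitrogen, ocd, ocs, phh2o, sand, silt,
#' soc) at 6 depths (0-5, 5-15, 15-30, 30-60, 60-100, 100-200 cm), i.e. 66
#' columns, drawn around plausible property-specific levels.
#'
#' @param states Character vector of state codes to cover.
#' @param seed Integer seed.
#' @return `data.frame` with a `state` column plus 66 numeric soil columns.
#' @export
synthetic_soil_table <- function(states, seed = 1L) {
  set.seed(as.integer(seed))
  props <- c(bdod = 140, cec = 25, cfvo = 8, clay = 25, nitrogen = 2.5,
             ocd = 35, ocs = 60, phh2o = 6.5, sand = 35, silt = 40, soc = 30)
  depths <- c("0-5", "5-15", "15-30", "30-60", "60-100", "100-200")
  states <- unique(states)
  out <- data.frame(state = states, stringsAsFactors = FALSE)
  for (p in names(props)) {
    for (d in depths) {
      out[[paste0(p, "_", d)]] <- props[[p]] * exp(rnorm(length(states), 0, 0.15))
    }
  }
  out
}
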