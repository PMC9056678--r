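# Endpoint-table handling: reading delimited files, the inorganic selection
# rules, solubility unit conversion, source merging, and train/test splits.

.endpoint_kinds <- c("BP", "MP", "PP", "logS")

# Elements screened out when deciding whether a compound qualifies as
# inorganic via "contains a metal": common organic-scaffold atoms, the
# frequent salt formers Na/Ca/K, and Si (organosilicons behave organically).
.nonmetal_screen <- c("C", "H", "O", "N", "F", "P", "S", "Cl", "Br", "I",
                      "Na", "Ca", "K", "Si")

#' Read an endpoint table
#'
#' Reads a UTF-8 CSV/TSV with a header containing at least `formula` and
#' `value` columns (optionally `temperature` for solubility records and
#' `source`).
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv`/`.tab` means tab, otherwise comma) unless given.
#' @param endpoint Endpoint tag attached to the records: one of
#'   `"BP"`, `"MP"`, `"PP"`, `"logS"`.
#' @param sep Optional explicit field separator.
#' @return A data.frame of endpoint records with columns `formula`, `value`,
#'   `endpoint`, `source` and, when present in the file, `temperature`.
#' @export
read_endpoint_table <- function(path, endpoint, sep = NULL) {
  endpoint <- match.arg(endpoint, .endpoint_kinds)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          check.names = FALSE)
  required <- c("formula", "value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("endpoint table '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value))) {
    stop("non-finite endpoint values in '", path, "'", call. = FALSE)
  }
  df$endpoint <- endpoint
  if (is.null(df$source)) df$source <- basename(path)
  df[, intersect(c("formula", "value", "endpoint", "source", "temperature"),
                 names(df)), drop = FALSE]
}

#' Inorganic / organometallic selection filter
#'
#' Keeps a record when its formula satisfies at least one of the selection
#' rules: (1) it contains no carbon, (2) it contains no hydrogen, or (3) it
#' contains a metal atom, where "metal" means any element outside the screen
#' set C, H, O, N, F, P, S, Cl, Br, I, Na, Ca, K, Si. Because Si belongs to
#' the screen set, organosilicon compounds (C and H plus Si only) do not
#' qualify and are removed. Unparseable formulas raise an error naming every
#' offending row rather than being dropped silently.
#'
#' @param records Data.frame with a `formula` column.
#' @return The filtered data.frame, with an added `inorganic_rule` column
#'   naming the first rule each kept record satisfied
#'   (`"no_carbon"`, `"no_hydrogen"`, `"metal"`).
#' @export
#' @examples
#' recs <- data.frame(formula = c("NaCl", "CH4", "Fe(CO)5"), value = 1:3)
#' inorganic_filter(recs)
inorganic_filter <- function(records) {
  stopifnot(is.data.frame(records), "formula" %in% names(records))
  failures <- character(0)
  rule <- character(nrow(records))
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    counts <- tryCatch(parse_formula(records$formula[i]), error = function(e) {
      failures[length(failures) + 1L] <<-
        paste0("row ", i, " ('", records$formula[i], "'): ",
               conditionMessage(e))
      NULL
    })
    if (is.null(counts)) next
    syms <- names(counts)
    if (!"C" %in% syms) {
      keep[i] <- TRUE; rule[i] <- "no_carbon"
    } else if (!"H" %in% syms) {
      keep[i] <- TRUE; rule[i] <- "no_hydrogen"
    } else if (any(!syms %in% .nonmetal_screen)) {
      keep[i] <- TRUE; rule[i] <- "metal"
    }
  }
  if (length(failures) > 0L) {
    stop("unparseable formulas in filter input:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  out <- records[keep, , drop = FALSE]
  out$inorganic_rule <- rule[keep]
  rownames(out) <- NULL
  out
}

#' Convert handbook water solubility to logS
#'
#' Handbook solubility is tabulated as grams of solute per 100 g of water.
#' Under the dilute approximation that 100 g of water occupies 0.1 L of
#' solution, molarity is `10 * w / mw` mol/L, and
#' `logS = log10(10 * w / mw)`.
#'
#' @param w Solubility in g per 100 g H2O (> 0).
#' @param mw Molecular weight in g/mol (> 0).
#' @return logS, the base-10 log of molar solubility. Vectorized.
#' @export
#' @examples
#' solubility_to_logS(36, molecular_weight("NaCl"))
solubility_to_logS <- function(w, mw) {
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("solubility w must be positive (log of a non-positive molarity is undefined)",
         call. = FALSE)
  }
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    stop("molecular weight must be positive", call. = FALSE)
  }
  log10(10 * w / mw)
}

#' Merge a curated primary source with a secondary source
#'
#' Union of the two record sets with the primary source authoritative: when a
#' formula occurs in both, the primary value is retained. Duplicate formulas
#' inside one source collapse to their first occurrence; value-conflicting
#' duplicates within the primary source are kept (first occurrence) but
#' reported in the attached conflict report.
#'
#' @param primary,secondary Data.frames of endpoint records sharing one
#'   endpoint kind (columns `formula`, `value`, ...).
#' @return Merged data.frame with attribute `"conflicts"`: a data.frame
#'   describing within-primary value conflicts and primary/secondary
#'   disagreements that were resolved.
#' @export
merge_sources <- function(primary, secondary) {
  stopifnot(is.data.frame(primary), is.data.frame(secondary))
  if ("endpoint" %in% names(primary) && "endpoint" %in% names(secondary) &&
      nrow(primary) > 0L && nrow(secondary) > 0L &&
      !identical(unique(primary$endpoint), unique(secondary$endpoint))) {
    stop("primary and secondary sources carry different endpoint kinds",
         call. = FALSE)
  }
  conflicts <- list()

  dedupe <- function(df, tag) {
    dup <- duplicated(df$formula)
    if (any(dup)) {
      for (f in unique(df$formula[dup])) {
        vals <- df$value[df$formula == f]
        if (length(unique(vals)) > 1L) {
          conflicts[[length(conflicts) + 1L]] <<- data.frame(
            formula = f, kind = paste0("duplicate_in_", tag),
            kept = vals[1L], dropped = paste(vals[-1L], collapse = ";"),
            stringsAsFactors = FALSE)
        }
      }
      df <- df[!dup, , drop = FALSE]
    }
    df
  }

  primary <- dedupe(primary, "primary")
  secondary <- dedupe(secondary, "secondary")

  overlap <- intersect(primary$formula, secondary$formula)
  if (length(overlap) > 0L) {
    p <- primary[match(overlap, primary$formula), ]
    s <- secondary[match(overlap, secondary$formula), ]
    diff <- p$value != s$value
    if (any(diff)) {
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        formula = overlap[diff], kind = "primary_over_secondary",
        kept = p$value[diff], dropped = as.character(s$value[diff]),
        stringsAsFactors = FALSE)
    }
  }

  merged <- rbind(primary,
                  secondary[!secondary$formula %in% primary$formula, ,
                            drop = FALSE])
  rownames(merged) <- NULL
  attr(merged, "conflicts") <- if (length(conflicts) > 0L) {
    do.call(rbind, conflicts)
  } else {
    data.frame(formula = character(0), kind = character(0),
               kept = numeric(0), dropped = character(0))
  }
  merged
}

#' Random train/test split
#'
#' Uniform random partition of the records, reproducible for a given seed.
#' Conventional ratios mirror the modelled endpoints: 0.1 test for the
#' smaller BP/PP sets, 0.2 for MP/logS.
#'
#' @param records Data.frame of endpoint records (>= 2 rows).
#' @param ratio Test fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratify_bins Optional integer: when given, sampling is stratified
#'   over this many equal-width bins of `value`.
#' @return An object of class `split_dataset`: list with `train`, `test`
#'   data.frames plus `seed` and `ratio`.
#' @export
split_dataset <- function(records, ratio, seed = 0L, stratify_bins = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L) stop("need at least 2 records to split", call. = FALSE)
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop("ratio must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(records)
  n_test <- max(1L, round(n * ratio))
  idx <- withr::with_seed(as.integer(seed), {
    if (is.null(stratify_bins)) {
      sample.int(n, n_test)
    } else {
      bins <- cut(records$value, breaks = stratify_bins, labels = FALSE,
                  include.lowest = TRUE)
      take <- unlist(lapply(split(seq_len(n), bins), function(ix) {
        k <- round(length(ix) * ratio)
        if (k > 0L) sample(ix, k) else integer(0)
      }), use.names = FALSE)
      take
    }
  })
  out <- list(train = records[-idx, , drop = FALSE],
              test = records[idx, , drop = FALSE],
              seed = as.integer(seed), ratio = ratio)
  rownames(out$train) <- NULL
  rownames(out$test) <- NULL
  class(out) <- "split_dataset"
  out
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("split_dataset: %d train / %d test (ratio %.2f, seed %d)\n",
              nrow(x$train), nrow(x$test), x$ratio, x$seed))
  invisible(x)
}

#' Write a split to train/test CSV files
#'
#' @param split A `split_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "split_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("train.csv", "test.csv"))
  utils::write.csv(split$train, paths[1L], row.names = FALSE)
  utils::write.csv(split$test, paths[2L], row.names = FALSE)
  invisible(paths)
}
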