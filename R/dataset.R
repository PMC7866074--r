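# Dataset schema: external CSV column names -> internal record names.
# The header comment line written by write_dataset() freezes the unit dialect.
.schema_version <- "tracerdiff-dataset v1"
.schema_units <- "T_K=K rho1_g_cm3=g.cm-3 mu1_cP=cP D12_cm2_s=cm2.s-1"
.core_cols <- c(solvent = "solvent_cas", solute = "solute_cas", T = "T_K",
                rho1 = "rho1_g_cm3", mu1 = "mu1_cP", D12 = "D12_cm2_s",
                polarity = "polarity", source = "source")
.prop_cols <- c("M1", "M2", "Tc1", "Tc2", "Tb1", "Tb2", "Pc1", "Pc2",
                "Vc1", "Vc2", "w1", "w2", "sigma1", "sigma2", "eps1", "eps2")

#' Read a diffusivity dataset from delimited text
#'
#' Reads a CSV in the documented schema (`solvent_cas, solute_cas, T_K,
#' rho1_g_cm3, mu1_cP, D12_cm2_s, polarity, source`, plus optional
#' per-record property columns `M1 ... eps2`), validates units-bearing
#' columns, and resolves any missing pure-compound properties by joining
#' against a compound table on CAS number or name. Lines starting with `#`
#' (the schema version header) are ignored.
#'
#' @param path Path to the CSV file.
#' @param compounds Compound table used to resolve missing property columns;
#'   defaults to the packaged [compound_table()]. Set to `NULL` to skip
#'   resolution (all property columns must then be present or absent
#'   knowingly).
#' @return A data.frame of records with internal column names
#'   (`solvent, solute, T, rho1, mu1, D12, polarity, source`, plus property
#'   columns).
#' @export
read_dataset <- function(path, compounds = compound_table()) {
  if (!file.exists(path)) .stop_domain("dataset file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(unname(.core_cols), names(df))
  if (length(missing)) {
    .stop_domain("dataset lacks required column(s): ",
                 paste(missing, collapse = ", "))
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    solvent = df[[.core_cols["solvent"]]],
                    solute = df[[.core_cols["solute"]]],
                    polarity = df[[.core_cols["polarity"]]],
                    source = df[[.core_cols["source"]]])
  for (v in c("T", "rho1", "mu1", "D12")) {
    out[[v]] <- .numeric_column(df[[.core_cols[v]]], .core_cols[v])
  }
  for (v in intersect(.prop_cols, names(df))) {
    out[[v]] <- .numeric_column(df[[v]], v)
  }
  bad <- which(out$T <= 0 | out$mu1 <= 0 | out$D12 <= 0)
  if (length(bad)) {
    .stop_domain(sprintf("non-positive T, mu1 or D12 in data row(s): %s",
                         paste(bad, collapse = ", ")))
  }
  if (any(!out$polarity %in% c("polar", "nonpolar"))) {
    bad <- which(!out$polarity %in% c("polar", "nonpolar"))
    .stop_domain("polarity must be 'polar' or 'nonpolar'; offending row(s): ",
                 paste(bad, collapse = ", "))
  }
  need <- setdiff(.prop_cols, names(out))
  if (length(need) && !is.null(compounds)) {
    out <- .resolve_properties(out, need, compounds)
  }
  out[c(names(.core_cols), intersect(.prop_cols, names(out)))]
}

.numeric_column <- function(x, name) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) | is.na(x))
  if (length(bad)) {
    .stop_domain(sprintf("non-numeric value in column '%s', data row(s): %s",
                         name, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  v
}

.resolve_properties <- function(out, need, compounds) {
  keys <- unique(c(out$solvent, out$solute))
  rows <- lapply(keys, function(k) lookup_compound(k, compounds))
  names(rows) <- keys
  pick <- function(key, field) vapply(rows[key], function(r) r[[field]], 0)
  field_of <- c(M = "M", Tc = "Tc", Tb = "Tb", Pc = "Pc", Vc = "Vc", w = "w",
                sigma = "sigma_lj", eps = "eps_lj_over_kB")
  for (col in need) {
    base <- sub("[12]$", "", col)
    side <- if (grepl("1$", col)) out$solvent else out$solute
    out[[col]] <- unname(pick(side, field_of[[base]]))
  }
  out
}

#' Write a diffusivity dataset to delimited text
#'
#' Writes records in the documented CSV schema, preceded by a schema-version
#' header line that freezes the unit dialect.
#'
#' @param records Data.frame of records as returned by [read_dataset()] or
#'   [generate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  df <- records
  for (i in seq_along(.core_cols)) {
    int <- names(.core_cols)[i]
    ext <- .core_cols[[i]]
    if (int %in% names(df) && !(ext %in% names(df))) {
      names(df)[names(df) == int] <- ext
    }
  }
  missing <- setdiff(unname(.core_cols), names(df))
  if (length(missing)) {
    .stop_domain("records lack required column(s): ",
                 paste(missing, collapse = ", "))
  }
  keep <- c(unname(.core_cols), intersect(.prop_cols, names(df)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s; units: %s", .schema_version, .schema_units), con)
  utils::write.csv(df[keep], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' System keys and system counts
#'
#' A "system" is a unique ordered (solvent, solute) pair; per-system
#' statistics (number of data points, AARD) are reported against these keys.
#'
#' @param records Data.frame with `solvent` and `solute` columns.
#' @return `system_key()`: character vector of keys, one per record.
#'   `n_systems()`: number of distinct systems.
#' @export
system_key <- function(records) {
  paste(records$solvent, records$solute, sep = " / ")
}

#' @rdname system_key
#' @export
n_systems <- function(records) {
  length(unique(system_key(records)))
}

#' Random record-level train/test split
#'
#' Splits records randomly into training and testing sets at the record level
#' (one system may contribute points to both sets), reproducibly under a
#' seed. The train size is `floor(fraction * n)`.
#'
#' @param records Data.frame of records (at least 2 rows).
#' @param fraction Training share in (0, 1); default 0.70.
#' @param seed Integer seed (required, and recorded in the result).
#' @return Object of class `d12_split`: list with `train`, `test`,
#'   `train_idx`, `seed`, `fraction`.
#' @export
#' @examples
#' rec <- data.frame(solvent = "a", solute = letters[1:10], T = 300,
#'                   mu1 = 1, D12 = 1e-5)
#' sp <- split_train_test(rec, 0.7, seed = 1)
#' nrow(sp$train); nrow(sp$test)
split_train_test <- function(records, fraction = 0.70, seed) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    .stop_domain("'fraction' must lie strictly inside (0, 1)")
  }
  n <- nrow(records)
  if (is.null(n) || n < 2L) .stop_domain("need at least 2 records to split")
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n_train <- floor(fraction * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  train_idx <- sort(sample.int(n, n_train))
  structure(list(train = records[train_idx, , drop = FALSE],
                 test = records[-train_idx, , drop = FALSE],
                 train_idx = train_idx,
                 seed = as.integer(seed), fraction = fraction),
            class = "d12_split")
}

#' @export
print.d12_split <- function(x, ...) {
  cat(sprintf("record-level split: %d train / %d test (fraction %.2f, seed %d)\n",
              nrow(x$train), nrow(x$test), x$fraction, x$seed))
  invisible(x)
}

# Preserve the caller's RNG stream around seeded internals.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Partition records by solvent polarity
#'
#' Splits a dataset into the polar and nonpolar sub-databases using the
#' per-record polarity label (a column of the data file, taken as ground
#' truth, not inferred from chemistry).
#'
#' @param records Data.frame with a `polarity` column.
#' @return List with elements `polar` and `nonpolar` (disjoint, exhaustive).
#' @export
partition_polarity <- function(records) {
  pol <- records$polarity
  if (is.null(pol) || any(is.na(pol)) || any(!nzchar(pol))) {
    .stop_domain("every record must carry a polarity label")
  }
  if (any(!pol %in% c("polar", "nonpolar"))) {
    .stop_domain("polarity labels must be 'polar' or 'nonpolar'")
  }
  list(polar = records[pol == "polar", , drop = FALSE],
       nonpolar = records[pol == "nonpolar", , drop = FALSE])
}
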