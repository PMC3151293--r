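#' Pedigrees as tibbles
#'
#' A pedigree is represented as a tibble with one row per individual and
#' columns `fam` (family label), `id`, `dadid`, `momid` (0 = founder),
#' `sex` (1 = male, 2 = female), `aff` (affection status: 1 = unaffected,
#' 2 = affected, 0 = unknown) and `seq` (1 if the member is sequenced in
#' stage I, 0 otherwise). This mirrors the whitespace-delimited LINKAGE
#' pre-makeped `.ped` layout with one optional trailing proband/sequenced
#' column.
#'
#' @name pedigree-format
NULL

.ped_cols <- c("fam", "id", "dadid", "momid", "sex", "aff", "seq")

new_pedigree <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"seq" %in% names(df)) df$seq <- 0L
  df <- df[, .ped_cols]
  class(df) <- c("pedigree_tbl", class(df))
  df
}

#' Validate a pedigree table
#'
#' Checks the structural invariants: unique ids within family, both parents
#' present or both absent, parent references resolvable, sexes of parents
#' consistent (father male, mother female), and acyclicity (no individual
#' is its own ancestor).
#'
#' @param ped A pedigree tibble (see [pedigree-format]).
#' @return Invisibly, `ped`; aborts with an informative message otherwise.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  missing_cols <- setdiff(setdiff(.ped_cols, "seq"), names(ped))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("pedigree lacks columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  for (f in unique(ped$fam)) {
    p <- ped[ped$fam == f, ]
    if (anyDuplicated(p$id)) {
      rlang::abort(sprintf("family %s: duplicated individual ids", f))
    }
    one_parent <- xor(p$dadid == 0, p$momid == 0)
    if (any(one_parent)) {
      rlang::abort(sprintf(
        "family %s: individuals %s have exactly one parent recorded",
        f, paste(p$id[one_parent], collapse = ", ")
      ))
    }
    for (col in c("dadid", "momid")) {
      ref <- p[[col]]
      bad <- ref != 0 & !(ref %in% p$id)
      if (any(bad)) {
        rlang::abort(sprintf(
          "family %s: individuals %s reference missing %s %s",
          f, paste(p$id[bad], collapse = ", "),
          if (col == "dadid") "father" else "mother",
          paste(ref[bad], collapse = ", ")
        ))
      }
    }
    dads <- p$dadid[p$dadid != 0]
    moms <- p$momid[p$momid != 0]
    if (any(p$sex[match(dads, p$id)] != 1)) {
      rlang::abort(sprintf("family %s: a father is not coded male", f))
    }
    if (any(p$sex[match(moms, p$id)] != 2)) {
      rlang::abort(sprintf("family %s: a mother is not coded female", f))
    }
    if (!all(p$sex %in% c(1, 2))) {
      rlang::abort(sprintf("family %s: unknown sex codes", f))
    }
    # acyclicity: iteratively strip founders-of-the-remainder
    remaining <- p$id
    repeat {
      sub <- p[p$id %in% remaining, ]
      leaves <- sub$id[!(sub$dadid %in% remaining) &
                         !(sub$momid %in% remaining)]
      if (length(leaves) == 0) break
      remaining <- setdiff(remaining, leaves)
    }
    if (length(remaining) > 0) {
      rlang::abort(sprintf(
        "family %s: cyclic ancestry involving individuals %s",
        f, paste(remaining, collapse = ", ")
      ))
    }
  }
  invisible(ped)
}

#' Read pedigrees from a LINKAGE pre-makeped file
#'
#' Parses whitespace-delimited columns `family id father mother sex
#' affection`, with an optional seventh column flagging sequenced members
#' (non-zero = sequenced). `0` marks missing parents; affection is coded
#' 1 = unaffected, 2 = affected, 0 = unknown. Lines beginning with `#` and
#' blank lines are ignored. Malformed rows are reported with their line
#' numbers.
#'
#' @param path Path to a `.ped` file.
#' @return A pedigree tibble (see [pedigree-format]); possibly several
#'   families.
#' @examples
#' ped <- read_ped(system.file("extdata", "fig1a.ped", package = "mpsdesign"))
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) rlang::abort(sprintf("%s: no pedigree records", path))
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!(length(fields) %in% c(6, 7))) {
      rlang::abort(sprintf("%s line %d: expected 6 or 7 fields, found %d",
                           path, i, length(fields)))
    }
    vals <- suppressWarnings(as.integer(fields[-1]))
    if (anyNA(vals)) {
      rlang::abort(sprintf("%s line %d: non-integer field", path, i))
    }
    tibble::tibble(
      fam = fields[1], id = vals[1], dadid = vals[2], momid = vals[3],
      sex = vals[4], aff = vals[5],
      seq = if (length(vals) >= 6) as.integer(vals[6] != 0) else 0L
    )
  })
  ped <- new_pedigree(dplyr::bind_rows(rows))
  if (!all(ped$aff %in% 0:2)) {
    rlang::abort(sprintf("%s: affection codes must be 0/1/2", path))
  }
  validate_pedigree(ped)
  ped
}

#' Write pedigrees to a LINKAGE pre-makeped file
#'
#' Inverse of [read_ped()]; `read_ped(write_ped(x, f))` restores `x`.
#'
#' @param ped A pedigree tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(ped, path) {
  validate_pedigree(ped)
  ped <- new_pedigree(ped)
  lines <- sprintf("%s %d %d %d %d %d %d", ped$fam, ped$id, ped$dadid,
                   ped$momid, ped$sex, ped$aff, ped$seq)
  writeLines(lines, path)
  invisible(path)
}

#' Split a multi-family pedigree table into a named list
#'
#' @param ped A pedigree tibble.
#' @return Named list of single-family pedigree tibbles.
#' @export
ped_families <- function(ped) {
  fams <- unique(ped$fam)
  stats::setNames(lapply(fams, function(f) new_pedigree(ped[ped$fam == f, ])),
                  fams)
}
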