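#' Construct a trio cohort from a member table
#'
#' A cohort is a set of families, each with one or two affected probands and
#' their parents. Monozygotic (MZ) twin probands are linked symmetrically via
#' `mz_twin_of`.
#'
#' @param members A data frame with columns `individual_id`, `family_id`,
#'   `father_id`, `mother_id` (`"0"` when absent), `sex` (`"male"`/`"female"`),
#'   `affected` (logical) and optionally `mz_twin_of` (`NA` when unlinked).
#' @return An object of class `trio_cohort`: a list with the validated
#'   `members` table (plus a derived `role` column) and `probands`, the
#'   proband id vector.
#' @export
cohort <- function(members) {
  required <- c("individual_id", "family_id", "father_id", "mother_id",
                "sex", "affected")
  missing_cols <- setdiff(required, names(members))
  if (length(missing_cols) > 0) {
    stop("pedigree table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  if (is.null(members$mz_twin_of)) members$mz_twin_of <- NA_character_
  members$individual_id <- as.character(members$individual_id)
  members$family_id <- as.character(members$family_id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)

  dup <- members$individual_id[duplicated(members$individual_id)]
  if (length(dup) > 0) {
    stop("duplicate individual id(s) in pedigree: ", paste(unique(dup), collapse = ", "))
  }
  if (!all(members$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }

  has_parents <- members$father_id != "0" & members$mother_id != "0"
  members$role <- ifelse(has_parents, "proband", NA_character_)
  members$role[members$individual_id %in% members$mother_id] <- "mother"
  members$role[members$individual_id %in% members$father_id] <- "father"
  if (anyNA(members$role)) {
    stop("individual(s) with no role (neither child nor parent): ",
         paste(members$individual_id[is.na(members$role)], collapse = ", "))
  }

  pro <- members[members$role == "proband", , drop = FALSE]
  for (i in seq_len(nrow(pro))) {
    fam <- members[members$family_id == pro$family_id[i], , drop = FALSE]
    if (!(pro$father_id[i] %in% fam$individual_id)) {
      stop(sprintf("family %s: father '%s' of proband '%s' not present",
                   pro$family_id[i], pro$father_id[i], pro$individual_id[i]))
    }
    if (!(pro$mother_id[i] %in% fam$individual_id)) {
      stop(sprintf("family %s: mother '%s' of proband '%s' not present",
                   pro$family_id[i], pro$mother_id[i], pro$individual_id[i]))
    }
  }

  # MZ twin links: symmetric, between probands of identical sex
  linked <- which(!is.na(members$mz_twin_of) & members$mz_twin_of != "0")
  for (i in linked) {
    twin <- members$mz_twin_of[i]
    j <- match(twin, members$individual_id)
    if (is.na(j)) stop("MZ twin id not in cohort: ", twin)
    if (!identical(members$mz_twin_of[j], members$individual_id[i])) {
      stop("MZ twin link not symmetric: ", members$individual_id[i], " / ", twin)
    }
    if (members$sex[i] != members$sex[j]) {
      stop("MZ twins must have identical sex: ", members$individual_id[i], " / ", twin)
    }
    if (members$role[i] != "proband" || members$role[j] != "proband") {
      stop("MZ twin links must join two probands")
    }
  }

  structure(list(members = members, probands = pro$individual_id),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  n_fam <- length(unique(x$members$family_id))
  twins <- mz_twin_pairs(x)
  cat(sprintf("trio_cohort: %d individuals, %d families, %d probands, %d MZ twin pair(s)\n",
              nrow(x$members), n_fam, length(x$probands), nrow(twins)))
  invisible(x)
}

#' Proband ids of a cohort
#' @param x A `trio_cohort`.
#' @return Character vector of proband ids.
#' @export
probands <- function(x) x$probands

#' Monozygotic twin pairs in a cohort
#' @param x A `trio_cohort`.
#' @return Data frame with columns `twin1`, `twin2`, one row per unordered pair.
#' @export
mz_twin_pairs <- function(x) {
  m <- x$members
  idx <- which(!is.na(m$mz_twin_of) & m$mz_twin_of != "0")
  pairs <- unique(t(apply(cbind(m$individual_id[idx], m$mz_twin_of[idx]), 1, sort)))
  if (length(pairs) == 0) {
    return(data.frame(twin1 = character(0), twin2 = character(0)))
  }
  data.frame(twin1 = pairs[, 1], twin2 = pairs[, 2], stringsAsFactors = FALSE)
}

#' Parents of a proband
#' @param x A `trio_cohort`.
#' @param proband_id A proband id.
#' @return List with `mother` and `father` ids.
#' @export
trio_parents <- function(x, proband_id) {
  i <- match(proband_id, x$members$individual_id)
  if (is.na(i)) stop("unknown individual: ", proband_id)
  list(mother = x$members$mother_id[i], father = x$members$father_id[i])
}

#' Sex of an individual
#' @param x A `trio_cohort`.
#' @param individual_id Individual id(s).
#' @return Character vector, `"male"`/`"female"`.
#' @export
member_sex <- function(x, individual_id) {
  x$members$sex[match(individual_id, x$members$individual_id)]
}

#' Read a pedigree file
#'
#' Reads the standard 6-column PED dialect (family, individual, father,
#' mother, sex coded 1/2, affection coded 1/2) with an optional 7th column
#' carrying monozygotic-twin links as `MZ:<twin_id>` (or `.` / `0` for none).
#' Standard PED has no twin notation, hence the extension column.
#'
#' @param path Path to a tab-separated PED file without header.
#' @return A [cohort()] object.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "#")
  if (ncol(raw) < 6) stop("PED file must have at least 6 columns")
  mz <- rep(NA_character_, nrow(raw))
  if (ncol(raw) >= 7) {
    tag <- raw[[7]]
    has <- grepl("^MZ:", tag)
    mz[has] <- sub("^MZ:", "", tag[has])
    bad <- !has & !(tag %in% c(".", "0", ""))
    if (any(bad)) stop("malformed twin column entries: ", paste(tag[bad], collapse = ", "))
  }
  sex_code <- raw[[5]]
  if (!all(sex_code %in% c("1", "2"))) stop("PED sex codes must be 1 (male) or 2 (female)")
  cohort(data.frame(
    individual_id = raw[[2]],
    family_id = raw[[1]],
    father_id = raw[[3]],
    mother_id = raw[[4]],
    sex = ifelse(sex_code == "1", "male", "female"),
    affected = raw[[6]] == "2",
    mz_twin_of = mz,
    stringsAsFactors = FALSE
  ))
}

#' Write a cohort as a PED file
#'
#' Inverse of [read_pedigree()]; a write/read round trip is the identity on
#' the member table.
#'
#' @param x A `trio_cohort`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(x, path) {
  m <- x$members
  out <- data.frame(
    m$family_id, m$individual_id, m$father_id, m$mother_id,
    ifelse(m$sex == "male", "1", "2"),
    ifelse(m$affected, "2", "1"),
    ifelse(is.na(m$mz_twin_of) | m$mz_twin_of == "0", ".",
           paste0("MZ:", m$mz_twin_of)),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated with header columns `proband_id`, `hpo_terms`
#' (semicolon-separated HPO identifiers) and `source` (one of
#' `ultrasound`, `postmortem`, `pediatric`). Terms are validated
#' syntactically (`HP:` followed by seven digits) and deduplicated.
#'
#' @param path Path to the TSV file.
#' @return Data frame with one row per proband: `proband_id`, `source` and a
#'   list-column `hpo_terms`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("proband_id", "hpo_terms", "source")
  if (!all(required %in% names(raw))) {
    stop("phenotype table must have columns: ", paste(required, collapse = ", "))
  }
  ok_src <- raw$source %in% c("ultrasound", "postmortem", "pediatric")
  if (!all(ok_src)) {
    stop("line ", which(!ok_src)[1] + 1L, ": invalid phenotype source '",
         raw$source[!ok_src][1], "'")
  }
  terms <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    tt <- strsplit(raw$hpo_terms[i], ";", fixed = TRUE)[[1]]
    tt <- tt[nzchar(tt) & tt != "."]
    bad <- tt[!grepl("^HP:[0-9]{7}$", tt)]
    if (length(bad) > 0) {
      stop("line ", i + 1L, ": malformed HPO term '", bad[1], "'")
    }
    terms[[i]] <- unique(tt)
  }
  data.frame(proband_id = raw$proband_id, source = raw$source,
             hpo_terms = I(terms), stringsAsFactors = FALSE)
}

#' Write a phenotype table
#'
#' @param phenotypes Data frame as returned by [read_phenotypes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  out <- data.frame(
    proband_id = phenotypes$proband_id,
    hpo_terms = vapply(phenotypes$hpo_terms, paste, "", collapse = ";"),
    source = phenotypes$source,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
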