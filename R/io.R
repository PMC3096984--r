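#' Read LD bin definitions
#'
#' Parses bin/tag-SNP definitions from either a generic tabular dialect or
#' ldSelect-style block output, one or more files (typically one per
#' population).
#'
#' The tabular dialect is a TSV with header
#' `bin_id  population  n_snps_in_bin  tag_snp_ids`, the last column holding
#' comma-separated candidate tag SNP ids. The ldSelect dialect parses blocks
#' of the form `Bin N ... TagSnps: ... OtherSnps: ...`; since those files do
#' not carry a population label, each file's population is taken from
#' `populations` (by default the file name without extension).
#'
#' @param paths Character vector of input file paths.
#' @param dialect `"tabular"` or `"ldselect"`.
#' @param populations For the ldSelect dialect, a character vector of
#'   population labels parallel to `paths`.
#' @return A tibble with one row per (bin, population): columns `bin_id`,
#'   `population`, `n_snps_in_bin` (the bin's total SNP membership) and
#'   `candidates` (list column of candidate tag SNP ids, duplicates
#'   collapsed).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("bin_id\tpopulation\tn_snps_in_bin\ttag_snp_ids",
#'              "bin1\tCEU\t5\trs1,rs2"), f)
#' read_bins(f)
#' @export
read_bins <- function(paths, dialect = c("tabular", "ldselect"),
                      populations = NULL) {
  dialect <- match.arg(dialect)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    bad_input(paste0("Bin file not found: ", paste(missing, collapse = ", ")))
  }
  if (dialect == "tabular") {
    out <- dplyr::bind_rows(lapply(paths, read_bins_tabular))
  } else {
    if (is.null(populations)) {
      populations <- sub("\\.[^.]*$", "", basename(paths))
    }
    if (length(populations) != length(paths)) {
      bad_input("`populations` must have one label per ldSelect file.")
    }
    out <- dplyr::bind_rows(
      Map(read_bins_ldselect, paths, populations)
    )
  }
  if (nrow(out) == 0) {
    return(tibble::tibble(bin_id = character(), population = character(),
                          n_snps_in_bin = integer(), candidates = list()))
  }
  dup <- duplicated(out[c("bin_id", "population")])
  if (any(dup)) {
    bad_input(paste0("Duplicate bin definition: ",
                     out$bin_id[dup][1], " / ", out$population[dup][1]))
  }
  out
}

read_bins_tabular <- function(path) {
  if (file.size(path) == 0) {
    return(tibble::tibble(bin_id = character(), population = character(),
                          n_snps_in_bin = integer(), candidates = list()))
  }
  tab <- tryCatch(
    suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
      bin_id = readr::col_character(),
      population = readr::col_character(),
      n_snps_in_bin = readr::col_integer(),
      tag_snp_ids = readr::col_character()
    ), progress = FALSE)),
    error = function(e) bad_input(paste0("Malformed bin file ", path, ": ",
                                         conditionMessage(e)))
  )
  need <- c("bin_id", "population", "n_snps_in_bin", "tag_snp_ids")
  if (!all(need %in% names(tab))) {
    bad_input(paste0("Bin file ", path, " must have columns ",
                     paste(need, collapse = ", "), "."))
  }
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    bad_input(paste0("Malformed line ", probs$row[1], " in ", path, ": ",
                     probs$expected[1], " but got ", probs$actual[1]))
  }
  bad <- which(is.na(tab$bin_id) | is.na(tab$population) |
                 is.na(tab$n_snps_in_bin))
  if (length(bad)) {
    bad_input(paste0("Malformed line ", bad[1] + 1L, " in ", path,
                     ": missing bin_id, population or n_snps_in_bin."))
  }
  tibble::tibble(
    bin_id = tab$bin_id,
    population = tab$population,
    n_snps_in_bin = tab$n_snps_in_bin,
    candidates = lapply(tab$tag_snp_ids, function(x) {
      if (is.na(x) || !nzchar(trimws(x))) return(character())
      unique(trimws(strsplit(x, ",", fixed = TRUE)[[1]]))
    })
  )
}

read_bins_ldselect <- function(path, population) {
  lines <- readLines(path, warn = FALSE)
  bins <- list()
  cur <- NULL
  flush_bin <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$tags)) {
      bad_input(paste0("ldSelect bin '", cur$bin_id, "' in ", path,
                       " has no TagSnps line (block starting at line ",
                       cur$line, ")."))
    }
    tibble::tibble(
      bin_id = cur$bin_id, population = population,
      n_snps_in_bin = length(cur$tags) + length(cur$others),
      candidates = list(unique(cur$tags))
    )
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s*Bin\\s+\\S+", ln)) {
      bins[[length(bins) + 1L]] <- flush_bin(cur)
      bin_id <- sub("^\\s*Bin\\s+(\\S+).*$", "\\1", ln)
      cur <- list(bin_id = bin_id, line = i,
                  tags = NULL, others = character())
    } else if (grepl("TagSnps\\s*:", ln)) {
      if (is.null(cur)) {
        bad_input(paste0("Malformed line ", i, " in ", path,
                         ": TagSnps outside a Bin block."))
      }
      cur$tags <- split_ids(sub("^.*TagSnps\\s*:", "", ln))
      if (length(cur$tags) == 0) {
        bad_input(paste0("Malformed line ", i, " in ", path,
                         ": TagSnps line lists no SNPs."))
      }
    } else if (grepl("OtherSnps\\s*:", ln)) {
      if (is.null(cur)) {
        bad_input(paste0("Malformed line ", i, " in ", path,
                         ": OtherSnps outside a Bin block."))
      }
      cur$others <- split_ids(sub("^.*OtherSnps\\s*:", "", ln))
    }
    # all other lines (average r^2, MAF summaries, ...) are ignored
  }
  bins[[length(bins) + 1L]] <- flush_bin(cur)
  out <- dplyr::bind_rows(bins)
  if (nrow(out) == 0) {
    return(tibble::tibble(bin_id = character(), population = character(),
                          n_snps_in_bin = integer(), candidates = list()))
  }
  out
}

split_ids <- function(x) {
  ids <- strsplit(trimws(x), "[\\s,]+", perl = TRUE)[[1]]
  ids[nzchar(ids)]
}

#' Write bin definitions in the tabular dialect
#'
#' The inverse of [read_bins()] for the tabular dialect; round-trips exactly.
#'
#' @param bins A bin tibble as returned by [read_bins()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bins <- function(bins, path) {
  out <- tibble::tibble(
    bin_id = bins$bin_id,
    population = bins$population,
    n_snps_in_bin = as.integer(bins$n_snps_in_bin),
    tag_snp_ids = vapply(bins$candidates, paste, "", collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a SNP annotation table
#'
#' A TSV with columns `snp_id`, `chrom`, `pos`, `allele1`, `allele2`,
#' `score`, `confidence_class`, `functional_class`. The vendor score sentinel
#' `-99` marks a missing score and is recorded as `NA`. Rows duplicated
#' verbatim are collapsed; duplicate ids with differing annotation are
#' rejected as ambiguous.
#'
#' @param path Path to the TSV.
#' @return A tibble with one row per SNP id, flag columns `is_obligate`,
#'   `is_excluded`, `is_pregenotyped` initialized to `FALSE`.
#' @export
read_snp_annotation <- function(path) {
  if (!file.exists(path)) bad_input(paste0("Annotation file not found: ", path))
  tab <- tryCatch(
    suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
      snp_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      allele1 = readr::col_character(),
      allele2 = readr::col_character(),
      score = readr::col_double(),
      confidence_class = readr::col_character(),
      functional_class = readr::col_character()
    ), progress = FALSE)),
    error = function(e) bad_input(paste0("Malformed annotation file ", path,
                                         ": ", conditionMessage(e)))
  )
  need <- c("snp_id", "chrom", "pos", "allele1", "allele2", "score",
            "confidence_class", "functional_class")
  if (!all(need %in% names(tab))) {
    bad_input(paste0("Annotation file must have columns ",
                     paste(need, collapse = ", "), "."))
  }
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    bad_input(paste0("Malformed line ", probs$row[1], " in ", path, ": ",
                     probs$expected[1], " but got ", probs$actual[1]))
  }
  tab <- dplyr::distinct(tab[need])
  dup <- duplicated(tab$snp_id)
  if (any(dup)) {
    bad_input(paste0("Conflicting duplicate annotation rows for SNP id ",
                     tab$snp_id[dup][1], "."))
  }
  validate_snps(tab)
}

#' Assemble a SNP annotation tibble from vectors
#'
#' Convenience constructor used by the synthetic generator and tests; applies
#' the same validation as [read_snp_annotation()].
#'
#' @param snp_id,chrom,pos,allele1,allele2,score,confidence_class,functional_class
#'   Parallel vectors describing one SNP per element; `score` may contain
#'   `NA` or the `-99` missing sentinel.
#' @return A validated SNP tibble.
#' @export
snp_table <- function(snp_id, chrom, pos, allele1, allele2, score,
                      confidence_class, functional_class) {
  validate_snps(tibble::tibble(
    snp_id = as.character(snp_id), chrom = as.character(chrom),
    pos = as.numeric(pos),
    allele1 = as.character(allele1), allele2 = as.character(allele2),
    score = as.numeric(score),
    confidence_class = as.character(confidence_class),
    functional_class = as.character(functional_class)
  ))
}

validate_snps <- function(tab) {
  tab$score[!is.na(tab$score) & tab$score == -99] <- NA_real_
  if (any(is.na(tab$pos)) || any(tab$pos < 1)) {
    bad_input("SNP positions must be 1-based coordinates >= 1.")
  }
  bases <- c("A", "C", "G", "T")
  bad <- !(toupper(tab$allele1) %in% bases) |
    !(toupper(tab$allele2) %in% bases) |
    toupper(tab$allele1) == toupper(tab$allele2)
  if (any(bad)) {
    bad_input(paste0("SNP ", tab$snp_id[bad][1],
                     " does not have two distinct alleles from {A,C,G,T}."))
  }
  tab$allele1 <- toupper(tab$allele1)
  tab$allele2 <- toupper(tab$allele2)
  for (fl in c("is_obligate", "is_excluded", "is_pregenotyped")) {
    if (is.null(tab[[fl]])) tab[[fl]] <- FALSE
  }
  tibble::as_tibble(tab)
}

#' Write a SNP annotation table
#'
#' Missing scores are written with the conventional `-99` sentinel.
#'
#' @param snps A SNP tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_snp_annotation <- function(snps, path) {
  out <- snps[c("snp_id", "chrom", "pos", "allele1", "allele2", "score",
                "confidence_class", "functional_class")]
  out$score[is.na(out$score)] <- -99
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a plain-text SNP id list
#'
#' One id per line; blank lines and `#` comments are ignored. Used for
#' obligate, excluded and previously genotyped SNP lists.
#'
#' @param path Path to the file.
#' @return A character vector of ids.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) bad_input(paste0("Id list not found: ", path))
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Apply user SNP lists to an annotation table
#'
#' Sets the `is_obligate`, `is_excluded` and `is_pregenotyped` flags and
#' checks for contradictions (an id both obligate and excluded, or unknown).
#'
#' @param snps A SNP tibble.
#' @param obligates,excluded,pregenotyped Character vectors of SNP ids (or
#'   `NULL`).
#' @return The flagged SNP tibble.
#' @export
flag_snps <- function(snps, obligates = NULL, excluded = NULL,
                      pregenotyped = NULL) {
  known <- snps$snp_id
  for (nm in c("obligates", "excluded", "pregenotyped")) {
    ids <- get(nm)
    unknown <- setdiff(ids, known)
    if (length(unknown)) {
      bad_input(paste0("Unknown SNP id in ", nm, " list: ",
                       paste(unknown, collapse = ", ")))
    }
  }
  both <- intersect(obligates, excluded)
  if (length(both)) {
    bad_input(paste0("SNP id(s) both obligate and excluded: ",
                     paste(both, collapse = ", ")))
  }
  snps$is_obligate <- snps$snp_id %in% obligates
  snps$is_excluded <- snps$snp_id %in% excluded
  snps$is_pregenotyped <- snps$snp_id %in% pregenotyped
  snps
}
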