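#' Locus definition table
#'
#' Builds the locus table carried by an [xy_dataset]. Each locus has a unique
#' name, a repeat-motif length in bp (used by the stepwise mutation model) and
#' an assumed inheritance class.
#'
#' @param name character vector of unique locus names.
#' @param motif_length integer vector (recycled), repeat unit length in bp,
#'   all `>= 1`.
#' @param assumed_class one of `"sex_linked"`, `"autosomal"`, `"unknown"`
#'   (recycled).
#' @return a `data.frame` with columns `name`, `motif_length`,
#'   `assumed_class`.
#' @export
locus_def <- function(name, motif_length = 2L, assumed_class = "unknown") {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("duplicate locus names")
  motif_length <- as.integer(rep_len(motif_length, length(name)))
  if (any(is.na(motif_length)) || any(motif_length < 1L))
    stop("motif_length must be an integer >= 1")
  assumed_class <- rep_len(as.character(assumed_class), length(name))
  bad <- !assumed_class %in% c("sex_linked", "autosomal", "unknown")
  if (any(bad)) stop("unknown assumed_class: ", assumed_class[bad][1])
  data.frame(name = name, motif_length = motif_length,
             assumed_class = assumed_class, stringsAsFactors = FALSE)
}

geno_cols <- function(loci) {
  as.vector(rbind(paste0(loci$name, ".a1"), paste0(loci$name, ".a2")))
}

#' Construct a genotyped-family dataset
#'
#' The central container: a locus table plus an individual table in the same
#' wide layout as the genotype CSV (see [read_genotype_table]). Alleles are
#' stored as integers: size in bp, `0` for a null (non-amplifying) allele,
#' `NA` for missing.
#'
#' @param loci a locus table from [locus_def].
#' @param ind a `data.frame` with columns `id`, `family`, `role`, `sex`,
#'   `species`, `population`, then `<locus>.a1`/`<locus>.a2` integer columns
#'   for every locus. `family` is `""` for unrelated adults.
#' @return an object of class `xy_dataset`.
#' @seealso [xy_families()], [read_genotype_table()], [validate_mendelian()]
#' @export
xy_dataset <- function(loci, ind) {
  stopifnot(is.data.frame(loci), is.data.frame(ind))
  meta_cols <- c("id", "family", "role", "sex", "species", "population")
  missing_meta <- setdiff(meta_cols, names(ind))
  if (length(missing_meta)) stop("ind lacks columns: ",
                                 paste(missing_meta, collapse = ", "))
  gc <- geno_cols(loci)
  missing_gc <- setdiff(gc, names(ind))
  if (length(missing_gc)) stop("ind lacks genotype columns: ",
                               paste(missing_gc, collapse = ", "))
  ind <- ind[, c(meta_cols, gc), drop = FALSE]
  for (cc in meta_cols) ind[[cc]] <- as.character(ind[[cc]])
  for (cc in gc) {
    v <- ind[[cc]]
    if (!is.numeric(v)) stop("genotype column ", cc, " is not numeric")
    iv <- as.integer(v)
    if (any(!is.na(v) & (v != iv | v < 0)))
      stop("genotype column ", cc, " has non-integer or negative allele sizes")
    ind[[cc]] <- iv
  }
  if (anyDuplicated(ind$id))
    stop("duplicate individual id: ", ind$id[duplicated(ind$id)][1])
  bad_role <- !ind$role %in% c("father", "mother", "offspring", "adult")
  if (any(bad_role)) stop("unknown role token: ", ind$role[bad_role][1])
  bad_sex <- !ind$sex %in% c("M", "F", "U")
  if (any(bad_sex)) stop("unknown sex token: ", ind$sex[bad_sex][1])
  if (any(ind$role == "father" & ind$sex != "M"))
    stop("fathers must have sex M")
  if (any(ind$role == "mother" & ind$sex != "F"))
    stop("mothers must have sex F")
  if (any(ind$role %in% c("father", "mother") & ind$family == ""))
    stop("parents must belong to a family")
  fams <- unique(ind$family[ind$family != ""])
  for (f in fams) {
    rows <- ind$role[ind$family == f]
    if (sum(rows == "father") != 1L || sum(rows == "mother") != 1L)
      stop("family ", f, " must have exactly one father and one mother")
    if (sum(rows == "offspring") < 1L)
      stop("family ", f, " has no offspring")
  }
  structure(list(loci = loci, ind = ind), class = "xy_dataset")
}

#' @export
print.xy_dataset <- function(x, ...) {
  nf <- length(unique(x$ind$family[x$ind$family != ""]))
  cat("<xy_dataset> ", nrow(x$loci), " loci, ", nf, " families, ",
      nrow(x$ind), " individuals (",
      sum(x$ind$role == "adult"), " unrelated adults)\n", sep = "")
  invisible(x)
}

#' Family index of a dataset
#'
#' @param dataset an [xy_dataset].
#' @return named list (one element per family) of lists with integer row
#'   indices `father`, `mother`, `offspring` into `dataset$ind`.
#' @export
xy_families <- function(dataset) {
  ind <- dataset$ind
  fams <- unique(ind$family[ind$family != ""])
  out <- lapply(fams, function(f) {
    in_f <- which(ind$family == f)
    list(father = in_f[ind$role[in_f] == "father"],
         mother = in_f[ind$role[in_f] == "mother"],
         offspring = in_f[ind$role[in_f] == "offspring"])
  })
  names(out) <- fams
  out
}

# Genotype of individual row i at locus (character name), as c(a1, a2).
get_geno <- function(dataset, i, locus) {
  c(dataset$ind[[paste0(locus, ".a1")]][i],
    dataset$ind[[paste0(locus, ".a2")]][i])
}

#' Read a genotype table
#'
#' Strict CSV dialect: header `id,family,role,sex,species,population` followed
#' by two columns per locus named `<locus>.a1`, `<locus>.a2`; `*` codes a null
#' allele, `NA` (or an empty field) a missing one; `family` is empty for
#' unrelated adults. Any malformed header, non-integer allele size, duplicate
#' id or unknown sex/role token raises an error naming the offending line.
#'
#' @param path path to the CSV file.
#' @param loci optional locus table from [locus_def] supplying motif lengths
#'   and inheritance classes (the CSV itself carries neither); defaults to
#'   motif length 2 and class `"unknown"` for every locus in the header.
#' @return an [xy_dataset].
#' @export
read_genotype_table <- function(path, loci = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty genotype table: ", path)
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  meta_cols <- c("id", "family", "role", "sex", "species", "population")
  if (length(hdr) < 8L || !identical(hdr[1:6], meta_cols))
    stop("line 1: malformed header (expected ",
         paste(meta_cols, collapse = ","), ",<locus>.a1,<locus>.a2,...)")
  gcols <- hdr[-(1:6)]
  if (length(gcols) %% 2L != 0L)
    stop("line 1: odd number of genotype columns")
  l1 <- sub("\\.a1$", "", gcols[seq(1, length(gcols), 2)])
  l2 <- sub("\\.a2$", "", gcols[seq(2, length(gcols), 2)])
  ok <- identical(l1, l2) &
    all(grepl("\\.a1$", gcols[seq(1, length(gcols), 2)])) &
    all(grepl("\\.a2$", gcols[seq(2, length(gcols), 2)]))
  if (!isTRUE(ok)) stop("line 1: genotype columns must come in ",
                        "<locus>.a1,<locus>.a2 pairs")
  if (is.null(loci)) loci <- locus_def(l1)
  if (!setequal(loci$name, l1))
    stop("locus table does not match the table header")
  loci <- loci[match(l1, loci$name), , drop = FALSE]
  rownames(loci) <- NULL

  body <- lines[-1]
  body <- body[body != ""]
  parse_allele <- function(tok, line_no) {
    out <- rep(NA_integer_, length(tok))
    out[tok == "*"] <- NULL_ALLELE
    num <- !(tok %in% c("*", "NA", ""))
    suppressWarnings(v <- as.integer(tok[num]))
    bad <- is.na(v) | v <= 0L | as.character(v) != tok[num]
    if (any(bad))
      stop("line ", line_no[num][bad][1], ": non-integer allele size '",
           tok[num][bad][1], "'")
    out[num] <- v
    out
  }
  nfield <- length(hdr)
  rows <- strsplit(body, ",", fixed = TRUE)
  lens <- lengths(rows)
  # trailing empty fields are dropped by strsplit; pad
  rows <- lapply(rows, function(r) c(r, rep("", nfield - length(r)))[1:nfield])
  if (any(lens > nfield))
    stop("line ", which(lens > nfield)[1] + 1L, ": too many fields")
  m <- do.call(rbind, rows)
  line_no <- seq_along(body) + 1L
  ind <- data.frame(id = m[, 1], family = m[, 2], role = m[, 3], sex = m[, 4],
                    species = m[, 5], population = m[, 6],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ind$id))
    stop("line ", line_no[duplicated(ind$id)][1], ": duplicate id '",
         ind$id[duplicated(ind$id)][1], "'")
  bad <- !ind$role %in% c("father", "mother", "offspring", "adult")
  if (any(bad)) stop("line ", line_no[bad][1], ": unknown role token '",
                     ind$role[bad][1], "'")
  bad <- !ind$sex %in% c("M", "F", "U")
  if (any(bad)) stop("line ", line_no[bad][1], ": unknown sex token '",
                     ind$sex[bad][1], "'")
  for (j in seq_along(gcols))
    ind[[gcols[j]]] <- parse_allele(m[, 6L + j], line_no)
  xy_dataset(loci, ind)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table]; emits the canonical form (rows in stored
#' order, nulls as `*`, missing as `NA`, no quoting), so that
#' write -> read -> write is byte-stable.
#'
#' @param dataset an [xy_dataset].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(dataset, path) {
  ind <- dataset$ind
  gc <- geno_cols(dataset$loci)
  fmt <- function(v) {
    out <- rep("NA", length(v))
    out[!is.na(v) & v == NULL_ALLELE] <- "*"
    sz <- !is.na(v) & v > 0L
    out[sz] <- as.character(v[sz])
    out
  }
  m <- cbind(ind$id, ind$family, ind$role, ind$sex, ind$species,
             ind$population,
             do.call(cbind, lapply(gc, function(cc) fmt(ind[[cc]]))))
  lines <- c(paste(c("id", "family", "role", "sex", "species", "population",
                     gc), collapse = ","),
             apply(m, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Check Mendelian consistency of all families
#'
#' For every offspring and locus, flags genotypes that are impossible given
#' the parents under the null-allele convention: a parent that is an apparent
#' homozygote (or carries an explicit `*`) may transmit a null allele, which
#' surfaces in the offspring as apparent homozygosity for the co-transmitted
#' allele; missing alleles are always compatible.
#'
#' @param dataset an [xy_dataset].
#' @param family optional character vector of family ids to check (default
#'   all).
#' @return `data.frame` with one row per violation: columns `family`,
#'   `offspring`, `locus`. Zero rows when the data are consistent.
#' @export
validate_mendelian <- function(dataset, family = NULL) {
  fams <- xy_families(dataset)
  if (!is.null(family)) fams <- fams[names(fams) %in% family]
  out <- list()
  for (fname in names(fams)) {
    fam <- fams[[fname]]
    for (locus in dataset$loci$name) {
      fg <- get_geno(dataset, fam$father, locus)
      mg <- get_geno(dataset, fam$mother, locus)
      ft <- transmissible_alleles(fg)
      mt <- transmissible_alleles(mg)
      for (o in fam$offspring) {
        og <- get_geno(dataset, o, locus)
        if (is_untyped(og)) next
        ok <- FALSE
        for (p in ft) {
          for (m in mt) {
            if (pair_obs_compat(p, m, og[1], og[2])) { ok <- TRUE; break }
          }
          if (ok) break
        }
        if (!ok)
          out[[length(out) + 1L]] <- data.frame(
            family = fname, offspring = dataset$ind$id[o], locus = locus,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(family = character(), offspring = character(),
                  locus = character(), stringsAsFactors = FALSE)
}

#' Pool several datasets into one
#'
#' Concatenates families and unrelated adults; species/population provenance
#' stays on each individual. Mirrors merging family files before building a
#' consensus map.
#'
#' @param groups list of [xy_dataset] objects sharing identical locus tables.
#' @return an [xy_dataset].
#' @export
pool_datasets <- function(groups) {
  stopifnot(length(groups) >= 1L)
  loci <- groups[[1]]$loci
  for (g in groups[-1]) {
    if (!identical(g$loci, loci))
      stop("conflicting locus definitions between pooled datasets")
  }
  inds <- lapply(seq_along(groups), function(i) {
    ind <- groups[[i]]$ind
    # keep ids/family labels unique across groups
    pre <- sprintf("g%d.", i)
    ind$id <- paste0(pre, ind$id)
    ind$family[ind$family != ""] <- paste0(pre, ind$family[ind$family != ""])
    ind
  })
  xy_dataset(loci, do.call(rbind, inds))
}
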