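## Phecode cohort construction from ICD event streams: map billing codes to
## phecodes, count distinct-date instances, and apply the case/control/
## exclusion and phenotype-retention rules.

.VOCABULARIES <- c("ICD9CM", "ICD10")

#' Read an ICD event table
#'
#' @param path CSV with columns `person_id`, `date` (ISO-8601), `code`,
#'   `vocabulary` (`ICD9CM` or `ICD10`).
#' @return data.frame of events with `date` as `Date`.
#' @export
readIcdEvents <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "date", "code", "vocabulary")
  if (!all(need %in% names(ev)))
    .configError(paste("ICD event table must have columns:",
                       paste(need, collapse = ", ")))
  ev$person_id <- as.character(ev$person_id)
  ev$date <- as.Date(ev$date)
  bad <- setdiff(unique(ev$vocabulary), .VOCABULARIES)
  if (length(bad))
    .validationError(paste("unknown vocabulary value(s):",
                           paste(bad, collapse = ", ")))
  ev
}

#' Read an ICD-to-phecode map
#'
#' @param path CSV with columns `icd`, `vocabulary`, `phecode`, `label`,
#'   `exclusion_min`, `exclusion_max`, `sex` (`none`, `male` or `female`).
#'   The exclusion range \[exclusion_min, exclusion_max\] is interpreted on
#'   the numeric phecode axis and must contain the phecode itself.
#' @return data.frame phecode map.
#' @export
readPhecodeMap <- function(path) {
  pm <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(phecode = "character"))
  need <- c("icd", "vocabulary", "phecode", "label", "exclusion_min",
            "exclusion_max", "sex")
  if (!all(need %in% names(pm)))
    .configError(paste("phecode map must have columns:",
                       paste(need, collapse = ", ")))
  bad <- setdiff(unique(pm$vocabulary), .VOCABULARIES)
  if (length(bad))
    .validationError(paste("unknown vocabulary value(s) in map:",
                           paste(bad, collapse = ", ")))
  outside <- as.numeric(pm$phecode) < pm$exclusion_min |
    as.numeric(pm$phecode) > pm$exclusion_max
  if (any(outside))
    .validationError("exclusion range must include the phecode itself")
  pm
}

#' Count phecode instances per person
#'
#' Maps ICD events through the phecode map and counts, per person and
#' phecode, distinct event dates: several codes for the same phecode on the
#' same day count once, so repeat billing within a visit cannot inflate case
#' status. Codes absent from the map are reported, not raised.
#'
#' @param events ICD event data.frame (see [readIcdEvents()]).
#' @param pmap phecode map data.frame (see [readPhecodeMap()]).
#' @return list with `counts` (data.frame `person_id`, `phecode`,
#'   `n_instances`) and `unmapped` (data.frame `code`, `vocabulary`,
#'   `n_events`).
#' @export
mapEventsToPhecodes <- function(events, pmap) {
  bad <- setdiff(unique(events$vocabulary), .VOCABULARIES)
  if (length(bad))
    .validationError(paste("unknown vocabulary value(s):",
                           paste(bad, collapse = ", ")))
  key_ev <- paste(events$code, events$vocabulary, sep = "|")
  key_map <- paste(pmap$icd, pmap$vocabulary, sep = "|")
  hit <- key_ev %in% key_map
  unmapped <- data.frame(code = character(0), vocabulary = character(0),
                         n_events = integer(0))
  if (any(!hit)) {
    tb <- table(key_ev[!hit])
    parts <- strsplit(names(tb), "|", fixed = TRUE)
    unmapped <- data.frame(code = vapply(parts, `[`, "", 1L),
                           vocabulary = vapply(parts, `[`, "", 2L),
                           n_events = as.integer(tb),
                           stringsAsFactors = FALSE)
  }
  ev <- events[hit, c("person_id", "code", "vocabulary", "date"), drop = FALSE]
  if (nrow(ev)) {
    # an ICD code may map to more than one phecode: merge expands
    expanded <- merge(ev, unique(pmap[, c("icd", "vocabulary", "phecode")]),
                      by.x = c("code", "vocabulary"),
                      by.y = c("icd", "vocabulary"))
    expanded <- unique(expanded[, c("person_id", "phecode", "date")])
    # same-day duplicates collapsed above; count distinct dates
    key <- paste(expanded$person_id, expanded$phecode, sep = "\r")
    tb <- table(key)
    parts <- strsplit(names(tb), "\r", fixed = TRUE)
    agg <- data.frame(person_id = vapply(parts, `[`, "", 1L),
                      phecode = vapply(parts, `[`, "", 2L),
                      n_instances = as.integer(tb),
                      stringsAsFactors = FALSE)
  } else {
    agg <- data.frame(person_id = character(0), phecode = character(0),
                      n_instances = integer(0))
  }
  list(counts = agg[order(agg$person_id, agg$phecode), , drop = FALSE],
       unmapped = unmapped)
}

## union of exclusion ranges, per phecode, as [min,max] intervals
.exclusionRanges <- function(pmap) {
  sp <- split(pmap, pmap$phecode)
  lapply(sp, function(d) unique(d[, c("exclusion_min", "exclusion_max")]))
}

#' Build a phecode case/control cohort
#'
#' Applies the PheWAS cohort rules to per-person phecode instance counts.
#' For every phecode: persons with at least `minCodeInstances` distinct-date
#' instances are cases; persons with an intermediate count (at least one but
#' fewer than `minCodeInstances`) or carrying any code in the phecode's
#' exclusion range are excluded; the remaining persons are controls, further
#' restricted to the age range (or birth-decade set) observed among the
#' cases. Phecodes with fewer than `minCases` cases, or restricted to a
#' single sex, are marked not retained and are skipped by [phewasScan()].
#'
#' @param counts `counts` element from [mapEventsToPhecodes()].
#' @param pmap phecode map data.frame.
#' @param demographics data.frame with `person_id`, `sex` and either `age`
#'   (numeric) or `birth_decade`, plus any covariate columns (e.g. PC1..PC5).
#'   Every person in `counts` must appear here; persons without any mapped
#'   event are control candidates.
#' @param minCases minimum case count for a phecode to be scanned
#'   (default 300).
#' @param minCodeInstances instances required for case status (default 2).
#' @return A [PhenomeCohort-class] object covering every phecode in `pmap`.
#' @export
buildCohort <- function(counts, pmap, demographics, minCases = 300,
                        minCodeInstances = 2) {
  if (minCases < 1 || minCodeInstances < 1)
    .configError("minCases and minCodeInstances must be >= 1")
  demographics$person_id <- as.character(demographics$person_id)
  missing <- setdiff(unique(counts$person_id), demographics$person_id)
  if (length(missing))
    .dataError(paste("person(s) in counts absent from demographics:",
                     paste(missing, collapse = ", ")))
  persons <- demographics$person_id
  phecodes <- sort(unique(pmap$phecode))
  cnt <- matrix(0L, nrow = length(persons), ncol = length(phecodes),
                dimnames = list(persons, phecodes))
  if (nrow(counts))
    cnt[cbind(match(counts$person_id, persons),
              match(counts$phecode, phecodes))] <- counts$n_instances
  phenum <- as.numeric(phecodes)
  ranges <- .exclusionRanges(pmap)
  age_col <- if ("age" %in% names(demographics)) "age"
             else if ("birth_decade" %in% names(demographics)) "birth_decade"
             else NULL
  sexmap <- vapply(split(pmap$sex, pmap$phecode), function(s) {
    s <- unique(s); if (length(s) > 1L) "mixed" else s
  }, "")
  status <- matrix(NA_integer_, nrow = length(persons),
                   ncol = length(phecodes),
                   dimnames = list(persons, phecodes))
  info <- data.frame(phecode = phecodes, stringsAsFactors = FALSE)
  info$label <- pmap$label[match(phecodes, pmap$phecode)]
  info$n_cases <- 0L; info$n_controls <- 0L; info$n_excluded <- 0L
  info$retained <- FALSE; info$drop_reason <- ""
  for (k in seq_along(phecodes)) {
    phi <- phecodes[k]
    c_phi <- cnt[, k]
    case <- c_phi >= minCodeInstances
    # exclusion-range carriers: any instance of any phecode inside the range
    rng <- ranges[[phi]]
    in_range <- rep(FALSE, length(phenum))
    for (r in seq_len(nrow(rng)))
      in_range <- in_range |
        (phenum >= rng$exclusion_min[r] & phenum <= rng$exclusion_max[r])
    carrier <- if (any(in_range))
      rowSums(cnt[, in_range, drop = FALSE] > 0) > 0 else rep(FALSE, length(persons))
    excl <- !case & (carrier | c_phi >= 1)
    ctrl <- !case & !excl
    # age (or birth-decade) matching: controls restricted to the case range
    if (!is.null(age_col) && any(case)) {
      av <- demographics[[age_col]]
      if (is.numeric(av)) {
        rngA <- range(av[case], na.rm = TRUE)
        ctrl <- ctrl & !is.na(av) & av >= rngA[1] & av <= rngA[2]
      } else {
        ctrl <- ctrl & av %in% unique(av[case])
      }
    }
    status[case, k] <- 1L
    status[ctrl, k] <- 0L
    info$n_cases[k] <- sum(case)
    info$n_controls[k] <- sum(ctrl)
    info$n_excluded[k] <- length(persons) - sum(case) - sum(ctrl)
    sx <- sexmap[phi]
    if (sx != "none") {
      info$drop_reason[k] <- "sex_restricted"
    } else if (sum(case) < minCases) {
      info$drop_reason[k] <- "too_few_cases"
    } else {
      info$retained[k] <- TRUE
    }
  }
  rownames(demographics) <- demographics$person_id
  methods::new("PhenomeCohort", status = status,
               demographics = demographics, phecodeInfo = info)
}
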