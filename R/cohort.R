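#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
NULL

#' Closed vocabularies of the lesion feature schema
#'
#' Category levels used throughout the package: tumor entities, clinical
#' subtypes, lesion morphology patterns on contrast-enhanced T1, and
#' anatomical locations.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
ENTITY_LEVELS <- c("mGB", "mCNSL")

#' @rdname vocabularies
#' @export
SUBTYPE_LEVELS <- c("multifocal", "multicentric", "PCNSL", "SCNSL", "unspecified")

#' @rdname vocabularies
#' @export
MORPHOLOGY_LEVELS <- c(
  "solid", "cystic_solid", "cystic", "cortical_infiltration",
  "stripe_or_tree", "extra_axial_nodular"
)

#' @rdname vocabularies
#' @export
LOCATION_LEVELS <- c(
  "frontal_lobe", "parietal_lobe", "temporal_lobe", "occipital_lobe",
  "diencephalon", "cerebral_peduncle", "brain_stem", "cerebellum",
  "corpus_callosum", "septum_pellucidum", "basal_ganglia",
  "internal_capsule", "insula", "ependymal_periventricular",
  "intraventricular", "leptomeningeal"
)

# Subtypes admissible for each entity. "unspecified" is always allowed.
subtypes_for_entity <- function(entity) {
  switch(entity,
    mGB   = c("multifocal", "multicentric", "unspecified"),
    mCNSL = c("PCNSL", "SCNSL", "unspecified"),
    character(0)
  )
}

# Canonical column order of a lesion cohort table (one row per lesion).
cohort_columns <- function() {
  c(
    "patient_id", "entity", "subtype", "perfusion_available",
    "swi_available", "lesion_id", "diameter_mm", "morphology", "location",
    "edema_mm", "nearest_lesion_distance_mm", "flair_connected",
    "contrast_enhancing",
    "adc_ratio_tumor", "adc_ratio_edema_5mm", "adc_ratio_edema_10mm",
    "adc_ratio_edema_20mm",
    "flair_ratio_tumor", "flair_ratio_edema_5mm", "flair_ratio_edema_10mm",
    "flair_ratio_edema_20mm",
    "rcbv_increased", "typical_curve", "swi_hemorrhage",
    "swi_vascularization"
  )
}

cohort_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    entity = readr::col_character(),
    subtype = readr::col_character(),
    perfusion_available = readr::col_logical(),
    swi_available = readr::col_logical(),
    lesion_id = readr::col_integer(),
    diameter_mm = readr::col_double(),
    morphology = readr::col_character(),
    location = readr::col_character(),
    edema_mm = readr::col_double(),
    nearest_lesion_distance_mm = readr::col_double(),
    flair_connected = readr::col_logical(),
    contrast_enhancing = readr::col_logical(),
    adc_ratio_tumor = readr::col_double(),
    adc_ratio_edema_5mm = readr::col_double(),
    adc_ratio_edema_10mm = readr::col_double(),
    adc_ratio_edema_20mm = readr::col_double(),
    flair_ratio_tumor = readr::col_double(),
    flair_ratio_edema_5mm = readr::col_double(),
    flair_ratio_edema_10mm = readr::col_double(),
    flair_ratio_edema_20mm = readr::col_double(),
    rcbv_increased = readr::col_logical(),
    typical_curve = readr::col_logical(),
    swi_hemorrhage = readr::col_logical(),
    swi_vascularization = readr::col_logical()
  )
}

#' Construct a lesion cohort table
#'
#' A cohort is a tibble with one row per tumor lesion; patient-level fields
#' (`entity`, `subtype`, `perfusion_available`, `swi_available`) are repeated
#' on every lesion row of that patient. Optional modality-dependent fields
#' (`rcbv_increased`, `typical_curve`, `swi_hemorrhage`,
#' `swi_vascularization`) and the more distant edema ratios are `NA` when
#' absent.
#'
#' @param lesions A data frame holding all columns of the schema (see
#'   [cohort_schema()]).
#' @param provenance Free-text provenance label (e.g. `"fixture"`,
#'   `"synthetic seed=1"`, or a file path).
#' @return A tibble of class `"lesion_cohort"` with a `provenance`
#'   attribute.
#' @export
as_cohort <- function(lesions, provenance = "unspecified") {
  lesions <- as_tibble(lesions)
  missing_cols <- setdiff(cohort_columns(), names(lesions))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      class = "lesiondx_schema_error"
    )
  }
  if (nrow(lesions) == 0) {
    abort("a cohort must contain at least one lesion", class = "lesiondx_schema_error")
  }
  bad_morph <- setdiff(unique(lesions$morphology), c(MORPHOLOGY_LEVELS, NA))
  if (length(bad_morph) > 0) {
    abort(
      paste0("unknown morphology token(s): ", paste(bad_morph, collapse = ", ")),
      class = "lesiondx_vocabulary_error"
    )
  }
  bad_loc <- setdiff(unique(lesions$location), c(LOCATION_LEVELS, NA))
  if (length(bad_loc) > 0) {
    abort(
      paste0("unknown location token(s): ", paste(bad_loc, collapse = ", ")),
      class = "lesiondx_vocabulary_error"
    )
  }
  out <- lesions[, cohort_columns()]
  out$lesion_id <- as.integer(out$lesion_id)
  attr(out, "provenance") <- provenance
  class(out) <- c("lesion_cohort", class(out))
  out
}

#' @rdname as_cohort
#' @param cohort A cohort table.
#' @export
provenance <- function(cohort) attr(cohort, "provenance")

#' Schema of the cohort table
#'
#' @return A tibble with one row per column of the cohort table: name,
#'   storage type, level (`patient` or `lesion`) and whether the field is
#'   optional (may be `NA`).
#' @export
cohort_schema <- function() {
  tibble(
    column = cohort_columns(),
    type = c(
      "character", "character", "character", "logical", "logical",
      "integer", "double", "character", "character", "double", "double",
      "logical", "logical", rep("double", 8), rep("logical", 4)
    ),
    level = c(
      "patient", "patient", "patient", "patient", "patient",
      rep("lesion", 20)
    ),
    optional = cohort_columns() %in% c(
      "adc_ratio_edema_10mm", "adc_ratio_edema_20mm",
      "flair_ratio_edema_10mm", "flair_ratio_edema_20mm",
      "rcbv_increased", "typical_curve", "swi_hemorrhage",
      "swi_vascularization"
    )
  )
}

#' One-row-per-patient view of a cohort
#'
#' @param cohort A cohort table.
#' @return A tibble with patient-level fields and `n_lesions`.
#' @export
patient_table <- function(cohort) {
  cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      entity = dplyr::first(.data$entity),
      subtype = dplyr::first(.data$subtype),
      perfusion_available = dplyr::first(.data$perfusion_available),
      swi_available = dplyr::first(.data$swi_available),
      n_lesions = dplyr::n(),
      .groups = "drop"
    )
}

#' Validate a cohort against the schema invariants
#'
#' Checks entity/subtype/morphology/location vocabularies, the 2-10 lesion
#' count rule, positivity of sizes and ratios, and the modality convention:
#' perfusion-dependent flags (`rcbv_increased`, `typical_curve`) must be set
#' on every lesion of a perfusion-available patient and absent otherwise,
#' and likewise for the SWI flags.
#'
#' @param cohort A cohort table.
#' @return A tibble of violations (`patient_id`, `field`, `rule`); empty
#'   when all invariants hold. This is a reporting operation and never
#'   throws.
#' @export
validate_cohort <- function(cohort) {
  v <- list()
  add <- function(pid, field, rule) {
    tibble(patient_id = as.character(pid), field = field, rule = rule)
  }

  for (pid in unique(cohort$patient_id)) {
    rows <- cohort[cohort$patient_id == pid, ]
    n_les <- nrow(rows)
    if (n_les < 2) v <- c(v, list(add(pid, "lesions", "lesion count < 2")))
    if (n_les > 10) v <- c(v, list(add(pid, "lesions", "lesion count > 10")))

    ent <- unique(rows$entity)
    if (length(ent) != 1 || !ent %in% ENTITY_LEVELS) {
      v <- c(v, list(add(pid, "entity", "entity must be a single value in {mGB, mCNSL}")))
    } else {
      sub <- unique(rows$subtype)
      if (length(sub) != 1 || !sub %in% subtypes_for_entity(ent)) {
        v <- c(v, list(add(pid, "subtype", paste0(
          "subtype must be consistent with entity ", ent
        ))))
      }
    }
    for (col in c("perfusion_available", "swi_available")) {
      val <- unique(rows[[col]])
      if (length(val) != 1 || anyNA(val)) {
        v <- c(v, list(add(pid, col, "patient-level flag must be a single non-missing value")))
      }
    }

    if (any(is.na(rows$diameter_mm) | rows$diameter_mm <= 0)) {
      v <- c(v, list(add(pid, "diameter_mm", "diameter must be > 0")))
    }
    if (any(is.na(rows$edema_mm) | rows$edema_mm < 0)) {
      v <- c(v, list(add(pid, "edema_mm", "edema extent must be >= 0")))
    }
    if (any(is.na(rows$nearest_lesion_distance_mm) |
              rows$nearest_lesion_distance_mm < 0)) {
      v <- c(v, list(add(pid, "nearest_lesion_distance_mm", "distance must be >= 0")))
    }
    if (any(!rows$morphology %in% MORPHOLOGY_LEVELS)) {
      v <- c(v, list(add(pid, "morphology", "morphology outside closed vocabulary")))
    }
    if (any(!rows$location %in% LOCATION_LEVELS)) {
      v <- c(v, list(add(pid, "location", "location outside closed vocabulary")))
    }
    for (col in c("flair_connected", "contrast_enhancing")) {
      if (anyNA(rows[[col]])) {
        v <- c(v, list(add(pid, col, "mandatory boolean field is missing")))
      }
    }
    ratio_cols <- grep("^(adc|flair)_ratio", cohort_columns(), value = TRUE)
    for (col in ratio_cols) {
      vals <- rows[[col]]
      if (any(!is.na(vals) & vals <= 0)) {
        v <- c(v, list(add(pid, col, "present ratios must be > 0")))
      }
    }
    mandatory_ratio <- c("adc_ratio_tumor", "adc_ratio_edema_5mm",
                         "flair_ratio_tumor", "flair_ratio_edema_5mm")
    for (col in mandatory_ratio) {
      if (anyNA(rows[[col]])) {
        v <- c(v, list(add(pid, col, "tumor and 5 mm ratios are mandatory")))
      }
    }

    perf <- isTRUE(rows$perfusion_available[1])
    for (col in c("rcbv_increased", "typical_curve")) {
      if (perf && anyNA(rows[[col]])) {
        v <- c(v, list(add(pid, col, "flag must be set when perfusion is available")))
      }
      if (!perf && any(!is.na(rows[[col]]))) {
        v <- c(v, list(add(pid, col, "flag must be absent when perfusion is unavailable")))
      }
    }
    swi <- isTRUE(rows$swi_available[1])
    for (col in c("swi_hemorrhage", "swi_vascularization")) {
      if (swi && anyNA(rows[[col]])) {
        v <- c(v, list(add(pid, col, "flag must be set when SWI is available")))
      }
      if (!swi && any(!is.na(rows[[col]]))) {
        v <- c(v, list(add(pid, col, "flag must be absent when SWI is unavailable")))
      }
    }
  }

  if (length(v) == 0) {
    tibble(patient_id = character(), field = character(), rule = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Write a cohort table to CSV or JSON
#'
#' CSV is one lesion per row with the canonical column order; absent
#' optional fields are written as empty cells. JSON nests lesions inside
#' patient records; absent fields are dropped from the lesion objects.
#' Output is deterministic: two writes of the same cohort are
#' byte-identical.
#'
#' @param cohort A valid cohort table.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    readr::write_csv(cohort[, cohort_columns()], path, na = "", progress = FALSE)
  } else {
    pats <- split(cohort, factor(cohort$patient_id, levels = unique(cohort$patient_id)))
    doc <- list(
      provenance = provenance(cohort) %||% "unspecified",
      patients = unname(lapply(pats, function(rows) {
        lesion_cols <- setdiff(cohort_columns(),
                               c("patient_id", "entity", "subtype",
                                 "perfusion_available", "swi_available"))
        lesions <- lapply(seq_len(nrow(rows)), function(i) {
          rec <- as.list(rows[i, lesion_cols])
          rec[!vapply(rec, is.na, logical(1))]
        })
        list(
          patient_id = rows$patient_id[1],
          entity = rows$entity[1],
          subtype = rows$subtype[1],
          perfusion_available = rows$perfusion_available[1],
          swi_available = rows$swi_available[1],
          lesions = lesions
        )
      }))
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort table from CSV or JSON
#'
#' Inverse of [write_cohort()]: `read_cohort(write_cohort(x, p), p)` returns
#' a cohort field-equal to `x`. Empty CSV cells and dropped JSON fields map
#' to absent (`NA`), never to zero.
#'
#' @param path Input file path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return A cohort table with provenance set to the file path (CSV) or the
#'   stored provenance (JSON).
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                    progress = FALSE, show_col_types = FALSE))
    missing_cols <- setdiff(cohort_columns(), header)
    if (length(missing_cols) > 0) {
      abort(
        paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
        class = "lesiondx_schema_error"
      )
    }
    df <- readr::read_csv(path, col_types = cohort_col_types(), na = "",
                          progress = FALSE, show_col_types = FALSE)
    as_cohort(df, provenance = paste0("file ", path))
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(doc$patients)) {
      abort("JSON cohort document must contain a 'patients' array",
            class = "lesiondx_schema_error")
    }
    lesion_cols <- setdiff(cohort_columns(),
                           c("patient_id", "entity", "subtype",
                             "perfusion_available", "swi_available"))
    schema <- cohort_schema()
    rows <- purrr::map_dfr(doc$patients, function(p) {
      purrr::map_dfr(p$lesions, function(les) {
        rec <- lapply(lesion_cols, function(col) {
          val <- les[[col]]
          if (is.null(val)) {
            type <- schema$type[schema$column == col]
            switch(type,
              double = NA_real_, integer = NA_integer_,
              logical = NA, character = NA_character_
            )
          } else {
            val
          }
        })
        names(rec) <- lesion_cols
        dplyr::bind_cols(
          tibble(
            patient_id = p$patient_id, entity = p$entity, subtype = p$subtype,
            perfusion_available = p$perfusion_available,
            swi_available = p$swi_available
          ),
          as_tibble(rec)
        )
      })
    })
    as_cohort(rows, provenance = doc$provenance %||% paste0("file ", path))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
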