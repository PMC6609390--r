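#' Rulebooks: the complete autoverification configuration
#'
#' A rulebook bundles every threshold the verification engine consults:
#' critical values, limited ranges, delta-check rules, whole-sample logical
#' rules, patient-context profiles, the QC gating policy and the clinical
#' reference intervals. [default_rulebook()] returns the configuration the
#' package ships for a routine four-assay coagulation panel;
#' [load_rulebook()] / [write_rulebook()] read and write the same structure
#' as a YAML document with an explicit `schema_version`. Loading is
#' fail-closed: unknown keys, malformed fields, or internally inconsistent
#' thresholds (for example a limited range reaching into critical territory)
#' abort with an error rather than yielding a partial rulebook.
#'
#' @section Default thresholds:
#' * Critical values: PT <= 9.00 s or >= 70.00 s, APTT <= 15.00 s or
#'   >= 100.00 s, TT > 150.00 s, FBG < 1.00 g/L. Inclusivity follows each
#'   rule as written (`<=`/`>=` for PT and APTT, strict for TT and FBG).
#' * Limited ranges (bounds inclusive): PT 11.00-16.30 s, APTT
#'   30.40-46.40 s, TT 14.00-21.00 s, FBG 2.00-6.51 g/L.
#' * Delta checks: PT |delta| < 10.00 s within 10 days; APTT |delta| <
#'   10.00 s within 7 days; FBG |delta| < 1.00 g/L within 3 days; TT has no
#'   delta rule. Under anticoagulant therapy with INR in 2.00-3.00 the
#'   PT/APTT window widens to 30 days.
#' * Logical rules L1-L3 (clot-pattern detection, see [logical_check()]).
#' * Context profiles: warfarin (PT upper limit 40.00 s plus an
#'   indication-specific allowable INR band), heparin (APTT upper limit
#'   90.00 s), thrombolytic therapy (FBG 1.20-4.00 g/L), late pregnancy
#'   (PT and APTT upper limits reduced 10%, FBG lower limit raised 10%).
#' * QC policy: newest control within 24 h, Westgard rejection rules
#'   1_3s, 2_2s, R_4s, 4_1s and 10_x (1_2s warns, never halts).
#' * Clinical reference intervals: PT 11.00-14.30 s, APTT 32.00-43.00 s,
#'   TT 14.00-21.00 s, FBG 2.00-4.00 g/L.
#'
#' @param path file path of a YAML rulebook document (or a single string
#'   containing YAML text for `load_rulebook`).
#' @param rb a `coag_rulebook` object.
#' @return `default_rulebook()` and `load_rulebook()` return a validated
#'   `coag_rulebook`; `rulebook_to_list()` a plain list mirroring the YAML
#'   document; `write_rulebook()` (invisibly) the path written.
#' @examples
#' rb <- default_rulebook()
#' rb$limited$PT
#' f <- tempfile(fileext = ".yaml")
#' write_rulebook(rb, f)
#' identical(rulebook_to_list(load_rulebook(f)), rulebook_to_list(rb))
#' @name rulebook
NULL

RULEBOOK_SCHEMA_VERSION <- 1L
CONTEXT_IDS <- c("none", "warfarin", "heparin", "thrombolytic", "late_pregnancy")
WARFARIN_INDICATIONS <- c("non_hip_surgery", "hip_surgery", "deep_vein_thrombosis",
                          "pulmonary_infarction", "arterial_thrombosis_prevention",
                          "valve_prosthesis")
WESTGARD_RULES <- c("1_2s", "1_3s", "2_2s", "R_4s", "4_1s", "10_x")

#' @rdname rulebook
#' @export
default_rulebook <- function() {
  rulebook_from_list(default_rulebook_list())
}

default_rulebook_list <- function() {
  list(
    schema_version = RULEBOOK_SCHEMA_VERSION,
    critical = list(
      PT   = list(low = 9.00,  high = 70.00,  low_inclusive = TRUE,  high_inclusive = TRUE),
      APTT = list(low = 15.00, high = 100.00, low_inclusive = TRUE,  high_inclusive = TRUE),
      TT   = list(high = 150.00, high_inclusive = FALSE),
      FBG  = list(low = 1.00, low_inclusive = FALSE)
    ),
    limited = list(
      PT   = c(11.00, 16.30),
      APTT = c(30.40, 46.40),
      TT   = c(14.00, 21.00),
      FBG  = c(2.00, 6.51)
    ),
    delta = list(
      PT   = list(max_abs_delta = 10.00, max_interval_days = 10L),
      APTT = list(max_abs_delta = 10.00, max_interval_days = 7L),
      FBG  = list(max_abs_delta = 1.00,  max_interval_days = 3L)
    ),
    anticoagulated_override = list(max_interval_days = 30L, inr_low = 2.00, inr_high = 3.00),
    logical = list(
      list(id = "L1", expr = "(PT >= 14.00 | APTT >= 43.00) & FBG <= 2.00"),
      list(id = "L2", expr = "PT >= 14.00 & APTT >= 43.00"),
      list(id = "L3", expr = "APTT <= 43.00 & PT <= 14.00 & TT >= 21.00")
    ),
    contexts = list(
      warfarin = list(
        replace = list(PT = list(upper = 40.00)),
        inr_allowable = list(
          non_hip_surgery = c(1.50, 2.50),
          hip_surgery = c(2.00, 3.00),
          deep_vein_thrombosis = c(2.00, 3.00),
          pulmonary_infarction = c(2.00, 4.00),
          arterial_thrombosis_prevention = c(3.00, 4.00),
          valve_prosthesis = c(3.00, 4.00)
        )
      ),
      heparin = list(replace = list(APTT = list(upper = 90.00))),
      thrombolytic = list(replace = list(FBG = list(lower = 1.20, upper = 4.00))),
      late_pregnancy = list(scale = list(PT = list(upper = 0.90),
                                         APTT = list(upper = 0.90),
                                         FBG = list(lower = 1.10)))
    ),
    qc_policy = list(
      max_qc_age_hours = 24,
      rejection_rules = c("1_3s", "2_2s", "R_4s", "4_1s", "10_x")
    ),
    reference_intervals = list(
      PT   = c(11.00, 14.30),
      APTT = c(32.00, 43.00),
      TT   = c(14.00, 21.00),
      FBG  = c(2.00, 4.00)
    )
  )
}

#' @rdname rulebook
#' @export
load_rulebook <- function(path) {
  x <- tryCatch(
    if (length(path) == 1L && !file.exists(path) && grepl("\n", path)) {
      yaml::yaml.load(path)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) stop_config("rulebook document does not parse as YAML: ",
                                    conditionMessage(e))
  )
  rulebook_from_list(x)
}

#' @rdname rulebook
#' @export
write_rulebook <- function(rb, path) {
  stopifnot(inherits(rb, "coag_rulebook"))
  yaml::write_yaml(rulebook_to_list(rb), path, precision = 12L)
  invisible(path)
}

#' @rdname rulebook
#' @export
rulebook_to_list <- function(rb) {
  stopifnot(inherits(rb, "coag_rulebook"))
  out <- unclass(rb)
  out$logical <- lapply(out$logical, function(r) list(id = r$id, expr = r$expr))
  out
}

#' @rdname rulebook
#' @export
rulebook_hash <- function(rb) {
  stopifnot(inherits(rb, "coag_rulebook"))
  rlang::hash(rulebook_to_list(rb))
}

#' @export
print.coag_rulebook <- function(x, ...) {
  cat("<coag_rulebook> schema v", x$schema_version, ", hash ", rulebook_hash(x), "\n", sep = "")
  for (a in analytes()) {
    lim <- x$limited[[a]]
    cat(sprintf("  %-4s limited [%.2f, %.2f] %s; critical %s\n", a, lim[1], lim[2],
                analyte_unit(a), format_critical(x$critical[[a]])))
  }
  cat("  delta rules:", paste(names(x$delta), collapse = ", "),
      "| contexts:", paste(setdiff(CONTEXT_IDS, "none"), collapse = ", "), "\n")
  cat("  logical rules:", paste(vapply(x$logical, `[[`, "", "id"), collapse = ", "), "\n")
  invisible(x)
}

format_critical <- function(cr) {
  parts <- character()
  if (!is.null(cr$low)) {
    parts <- c(parts, paste0(if (isTRUE(cr$low_inclusive)) "<= " else "< ", format(cr$low)))
  }
  if (!is.null(cr$high)) {
    parts <- c(parts, paste0(if (isTRUE(cr$high_inclusive)) ">= " else "> ", format(cr$high)))
  }
  paste(parts, collapse = " or ")
}

# ---- construction + validation --------------------------------------------

rulebook_from_list <- function(x) {
  if (!is.list(x)) stop_config("rulebook document must be a mapping at the top level")
  allowed <- c("schema_version", "critical", "limited", "delta",
               "anticoagulated_override", "logical", "contexts", "qc_policy",
               "reference_intervals")
  check_keys(x, allowed, path = "rulebook",
             required = allowed)
  if (!identical(as.integer(x$schema_version), RULEBOOK_SCHEMA_VERSION)) {
    stop_config("unsupported schema_version: ", x$schema_version,
                " (this package reads version ", RULEBOOK_SCHEMA_VERSION, ")")
  }

  rb <- list(schema_version = RULEBOOK_SCHEMA_VERSION)
  rb$critical <- validate_critical(x$critical)
  rb$limited <- validate_ranges(x$limited, "limited")
  rb$delta <- validate_delta(x$delta)
  rb$anticoagulated_override <- validate_override(x$anticoagulated_override)
  rb$logical <- validate_logical(x$logical)
  rb$contexts <- validate_contexts(x$contexts)
  rb$qc_policy <- validate_qc_policy(x$qc_policy)
  rb$reference_intervals <- validate_ranges(x$reference_intervals, "reference_intervals")

  # cross-field consistency: every limited range strictly inside the critical band
  for (a in analytes()) {
    check_inside_critical(rb$limited[[a]], rb$critical[[a]], paste0("limited.", a))
  }
  # context replacements must also stay clear of critical territory
  for (cid in names(rb$contexts)) {
    eff <- apply_context(rb$limited, rb$contexts[[cid]])
    for (a in analytes()) {
      check_inside_critical(eff[[a]], rb$critical[[a]],
                            paste0("contexts.", cid, " effective ", a, " range"))
    }
  }
  structure(rb, class = "coag_rulebook")
}

check_keys <- function(x, allowed, path, required = character()) {
  if (!is.list(x)) stop_config("expected a mapping", path = path)
  nm <- names(x)
  if (is.null(nm) || any(nm == "")) stop_config("all entries must be named", path = path)
  unknown <- setdiff(nm, allowed)
  if (length(unknown)) {
    stop_config("unknown key(s): ", paste(unknown, collapse = ", "), path = path)
  }
  missing <- setdiff(required, nm)
  if (length(missing)) {
    stop_config("missing required key(s): ", paste(missing, collapse = ", "), path = path)
  }
  invisible(x)
}

validate_critical <- function(x) {
  check_keys(x, analytes(), "critical", required = analytes())
  out <- list()
  for (a in analytes()) {
    cr <- x[[a]]
    check_keys(cr, c("low", "high", "low_inclusive", "high_inclusive"),
               paste0("critical.", a))
    if (is.null(cr$low) && is.null(cr$high)) {
      stop_config("at least one of low/high must be present", path = paste0("critical.", a))
    }
    for (f in c("low", "high")) {
      if (!is.null(cr[[f]]) && !is_scalar_number(cr[[f]])) {
        stop_config(f, " must be a finite number", path = paste0("critical.", a))
      }
    }
    if (!is.null(cr$low) && !is.null(cr$high) && !(cr$low < cr$high)) {
      stop_config("low must be < high", path = paste0("critical.", a))
    }
    out[[a]] <- list(
      low = cr$low, high = cr$high,
      low_inclusive = if (is.null(cr$low)) NULL else isTRUE(cr$low_inclusive),
      high_inclusive = if (is.null(cr$high)) NULL else isTRUE(cr$high_inclusive)
    )
  }
  out
}

validate_ranges <- function(x, what) {
  check_keys(x, analytes(), what, required = analytes())
  out <- list()
  for (a in analytes()) {
    r <- as.numeric(unlist(x[[a]]))
    if (length(r) != 2L || anyNA(r) || !all(is.finite(r))) {
      stop_config("must be a [lower, upper] pair of finite numbers", path = paste0(what, ".", a))
    }
    if (!(r[1] < r[2])) stop_config("lower must be < upper", path = paste0(what, ".", a))
    out[[a]] <- r
  }
  out
}

validate_delta <- function(x) {
  check_keys(x, setdiff(analytes(), character()), "delta")
  out <- list()
  for (a in names(x)) {
    d <- x[[a]]
    check_keys(d, c("max_abs_delta", "max_interval_days"), paste0("delta.", a),
               required = c("max_abs_delta", "max_interval_days"))
    if (!is_scalar_number(d$max_abs_delta) || d$max_abs_delta <= 0) {
      stop_config("max_abs_delta must be > 0", path = paste0("delta.", a))
    }
    days <- d$max_interval_days
    if (!is_scalar_number(days) || days <= 0 || days != as.integer(days)) {
      stop_config("max_interval_days must be a positive integer", path = paste0("delta.", a))
    }
    out[[a]] <- list(max_abs_delta = as.numeric(d$max_abs_delta),
                     max_interval_days = as.integer(days))
  }
  out
}

validate_override <- function(x) {
  check_keys(x, c("max_interval_days", "inr_low", "inr_high"), "anticoagulated_override",
             required = c("max_interval_days", "inr_low", "inr_high"))
  if (!is_scalar_number(x$max_interval_days) || x$max_interval_days <= 0) {
    stop_config("max_interval_days must be > 0", path = "anticoagulated_override")
  }
  if (!is_scalar_number(x$inr_low) || !is_scalar_number(x$inr_high) ||
      !(x$inr_low < x$inr_high)) {
    stop_config("inr_low must be < inr_high", path = "anticoagulated_override")
  }
  list(max_interval_days = as.integer(x$max_interval_days),
       inr_low = as.numeric(x$inr_low), inr_high = as.numeric(x$inr_high))
}

# a logical-rule expression may reference only panel analytes, comparison
# operators, logical connectives and numeric literals — anything else is a
# config error (the expressions are evaluated, so this is a safety fence too)
validate_logical <- function(x) {
  if (!is.list(x) || length(x) == 0L) stop_config("logical: need a non-empty rule list")
  ids <- character()
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    r <- x[[i]]
    check_keys(r, c("id", "expr"), paste0("logical[", i, "]"), required = c("id", "expr"))
    if (!is.character(r$id) || length(r$id) != 1L || !nzchar(r$id)) {
      stop_config("id must be a non-empty string", path = paste0("logical[", i, "]"))
    }
    if (r$id %in% ids) stop_config("duplicate rule id: ", r$id, path = "logical")
    ids <- c(ids, r$id)
    expr <- tryCatch(str2lang(r$expr),
                     error = function(e) stop_config("expr does not parse: ", r$expr,
                                                     path = paste0("logical.", r$id)))
    syms <- all.names(expr)
    allowed <- c(analytes(), "INR", "(", "&", "|", "&&", "||", "!",
                 ">", ">=", "<", "<=", "==", "!=")
    bad <- setdiff(syms, allowed)
    if (length(bad)) {
      stop_config("expr uses disallowed symbol(s): ", paste(bad, collapse = ", "),
                  path = paste0("logical.", r$id))
    }
    out[[i]] <- list(id = r$id, expr = r$expr, parsed = expr)
  }
  out
}

validate_contexts <- function(x) {
  check_keys(x, setdiff(CONTEXT_IDS, "none"), "contexts")
  out <- list()
  for (cid in names(x)) {
    ctx <- x[[cid]]
    check_keys(ctx, c("replace", "scale", "inr_allowable"), paste0("contexts.", cid))
    prof <- list()
    if (!is.null(ctx$replace)) {
      check_keys(ctx$replace, analytes(), paste0("contexts.", cid, ".replace"))
      prof$replace <- lapply(ctx$replace, function(r) {
        check_keys(r, c("lower", "upper"), paste0("contexts.", cid, ".replace"))
        lapply(r, function(v) {
          if (!is_scalar_number(v)) stop_config("replacement bounds must be numbers",
                                                path = paste0("contexts.", cid))
          as.numeric(v)
        })
      })
    }
    if (!is.null(ctx$scale)) {
      check_keys(ctx$scale, analytes(), paste0("contexts.", cid, ".scale"))
      prof$scale <- lapply(ctx$scale, function(r) {
        check_keys(r, c("lower", "upper"), paste0("contexts.", cid, ".scale"))
        lapply(r, function(v) {
          if (!is_scalar_number(v) || v <= 0) stop_config("scale factors must be > 0",
                                                          path = paste0("contexts.", cid))
          as.numeric(v)
        })
      })
    }
    if (!is.null(ctx$inr_allowable)) {
      check_keys(ctx$inr_allowable, WARFARIN_INDICATIONS,
                 paste0("contexts.", cid, ".inr_allowable"),
                 required = WARFARIN_INDICATIONS)
      prof$inr_allowable <- lapply(ctx$inr_allowable, function(v) {
        v <- as.numeric(unlist(v))
        if (length(v) != 2L || anyNA(v) || !(v[1] < v[2])) {
          stop_config("each INR band must be [low, high] with low < high",
                      path = paste0("contexts.", cid, ".inr_allowable"))
        }
        v
      })
    }
    out[[cid]] <- prof
  }
  out
}

validate_qc_policy <- function(x) {
  check_keys(x, c("max_qc_age_hours", "rejection_rules"), "qc_policy",
             required = c("max_qc_age_hours", "rejection_rules"))
  if (!is_scalar_number(x$max_qc_age_hours) || x$max_qc_age_hours <= 0) {
    stop_config("max_qc_age_hours must be > 0", path = "qc_policy")
  }
  rules <- as.character(unlist(x$rejection_rules))
  bad <- setdiff(rules, WESTGARD_RULES)
  if (length(bad)) {
    stop_config("unknown Westgard rule id(s): ", paste(bad, collapse = ", "),
                path = "qc_policy.rejection_rules")
  }
  list(max_qc_age_hours = as.numeric(x$max_qc_age_hours), rejection_rules = rules)
}

# value-level critical test used both by validation and the engine
is_critical_value <- function(value, cr) {
  if (!is.null(cr$low)) {
    if (if (isTRUE(cr$low_inclusive)) value <= cr$low else value < cr$low) return(TRUE)
  }
  if (!is.null(cr$high)) {
    if (if (isTRUE(cr$high_inclusive)) value >= cr$high else value > cr$high) return(TRUE)
  }
  FALSE
}

# limited ranges must sit strictly between the critical thresholds so that a
# value passing the range check can never simultaneously be critical
check_inside_critical <- function(range, cr, path) {
  if (!is.null(cr$low) && !(range[1] > cr$low)) {
    stop_config(sprintf("lower bound %.2f does not clear the low critical threshold %.2f",
                        range[1], cr$low), path = path)
  }
  if (!is.null(cr$high) && !(range[2] < cr$high)) {
    stop_config(sprintf("upper bound %.2f reaches the high critical threshold %.2f",
                        range[2], cr$high), path = path)
  }
  invisible(TRUE)
}

# apply replacements then multiplicative adjustments to a set of limited
# ranges; scaled bounds are rounded to 2 decimals (the lab's reporting
# precision)
apply_context <- function(limited, profile) {
  eff <- limited
  for (a in names(profile$replace %||% list())) {
    r <- profile$replace[[a]]
    if (!is.null(r$lower)) eff[[a]][1] <- r$lower
    if (!is.null(r$upper)) eff[[a]][2] <- r$upper
  }
  for (a in names(profile$scale %||% list())) {
    s <- profile$scale[[a]]
    if (!is.null(s$lower)) eff[[a]][1] <- round_half_up(eff[[a]][1] * s$lower, 2)
    if (!is.null(s$upper)) eff[[a]][2] <- round_half_up(eff[[a]][2] * s$upper, 2)
  }
  for (a in names(eff)) {
    if (!(eff[[a]][1] < eff[[a]][2])) {
      stop_config("context adjustment produced an empty range for ", a)
    }
  }
  eff
}

#' Resolve effective per-analyte limits for a patient context
#'
#' Applies a context profile (anticoagulant therapy, thrombolytic therapy,
#' late pregnancy) to the rulebook's routine limited ranges. Replacements are
#' applied first, then multiplicative adjustments (late pregnancy), with
#' adjusted bounds rounded to 2 decimals. Exactly one context applies per
#' sample; combined contexts must be encoded as their own profile.
#'
#' @param rb a `coag_rulebook`.
#' @param context one of `"none"`, `"warfarin"`, `"heparin"`,
#'   `"thrombolytic"`, `"late_pregnancy"`.
#' @param warfarin_indication required when `context = "warfarin"`: one of
#'   `"non_hip_surgery"`, `"hip_surgery"`, `"deep_vein_thrombosis"`,
#'   `"pulmonary_infarction"`, `"arterial_thrombosis_prevention"`,
#'   `"valve_prosthesis"`. Selects the allowable INR band.
#' @return a list with `limited` (named list of `[lower, upper]` per analyte),
#'   `inr_allowable` (`[low, high]` or `NULL`), `anticoagulated` (logical;
#'   TRUE for the warfarin and heparin profiles, which activates the widened
#'   delta-check window when INR is in band) and `context`.
#' @examples
#' eff <- resolve_context(default_rulebook(), "late_pregnancy")
#' eff$limited$PT  # upper bound tightened by 10%
#' @export
resolve_context <- function(rb, context = "none", warfarin_indication = NULL) {
  stopifnot(inherits(rb, "coag_rulebook"))
  if (!(is.character(context) && length(context) == 1L && context %in% CONTEXT_IDS)) {
    stop_config("unknown context: ", paste(context, collapse = "+"),
                " (one context per sample; accepted: ",
                paste(CONTEXT_IDS, collapse = ", "), ")")
  }
  if (context == "none") {
    return(list(limited = rb$limited, inr_allowable = NULL,
                anticoagulated = FALSE, context = "none"))
  }
  profile <- rb$contexts[[context]]
  if (is.null(profile)) stop_config("context not configured in rulebook: ", context)
  inr <- NULL
  if (!is.null(profile$inr_allowable)) {
    if (is.null(warfarin_indication)) {
      stop_config("context '", context, "' requires a warfarin_indication ",
                  "(one of ", paste(WARFARIN_INDICATIONS, collapse = ", "), ")")
    }
    if (!(warfarin_indication %in% WARFARIN_INDICATIONS)) {
      stop_config("unknown warfarin_indication: ", warfarin_indication)
    }
    inr <- profile$inr_allowable[[warfarin_indication]]
  }
  list(limited = apply_context(rb$limited, profile),
       inr_allowable = inr,
       anticoagulated = context %in% c("warfarin", "heparin"),
       context = context)
}
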