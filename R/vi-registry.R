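#' Vegetation-index registry
#'
#' The package maintains a registry of named vegetation-index (VI) formulas
#' over the five sensor bands. All built-in indices are registered when the
#' package loads; [register_vi()] adds custom ones, either as an R function
#' of the bands or as a formula string over the symbols `B`, `G`, `R`, `RE`,
#' `NIR` parsed by a small safe arithmetic grammar.
#'
#' Narrowband-defined indices (mND705, mSR705, SR445, ...) are expressed on
#' the sensor bands through the fixed wavelength mapping of [resolve_band()]:
#' 445 nm -> blue, 705 nm -> rededge, 750/800 nm -> nir. Constants follow the
#' canonical published forms: SAVI L = 0.5, OSAVI 0.16, WDRVI alpha = 0.2,
#' EVI (G, C1, C2, L) = (2.5, 6, 7.5, 1).
#'
#' @name vi_registry
NULL

.vi_registry <- new.env(parent = emptyenv())

new_vi_definition <- function(name, required_bands, fun, reference = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            all(required_bands %in% band_names()), is.function(fun))
  structure(list(name = name, required_bands = required_bands,
                 fun = fun, reference = reference),
            class = "vi_definition")
}

canonical_vi_name <- function(name) {
  # file-safe canonical form; lookup is case-insensitive
  gsub("/", "_", name, fixed = TRUE)
}

#' Register a vegetation index
#'
#' @param name Canonical index name (case preserved for display; lookups are
#'   case-insensitive; `/` is canonicalized to `_`, so "TCARI/OSAVI" is
#'   stored as "TCARI_OSAVI").
#' @param formula Either a function taking a named band vector/list (with
#'   elements `blue`, `green`, `red`, `rededge`, `nir`) or a formula string
#'   over `B`, `G`, `R`, `RE`, `NIR` using `+ - * / ^ sqrt()` and numbers.
#' @param required_bands Bands the formula reads; inferred from the string
#'   form, mandatory for the function form.
#' @param reference Free-text provenance tag.
#' @param overwrite Replace an existing registration?
#' @return The canonical name, invisibly.
#' @examples
#' register_vi("SRdemo", "NIR / RE", reference = "simple ratio demo",
#'             overwrite = TRUE)
#' compute_vi("SRdemo", c(rededge = 0.25, nir = 0.5))
#' @export
register_vi <- function(name, formula, required_bands = NULL,
                        reference = "", overwrite = FALSE) {
  cname <- canonical_vi_name(name)
  key <- tolower(cname)
  if (!overwrite && key %in% ls(.vi_registry)) {
    stop("VI already registered: ", cname, " (use overwrite = TRUE)")
  }
  if (is.character(formula)) {
    parsed <- parse_vi_formula(formula)
    fun <- parsed$fun
    if (is.null(required_bands)) required_bands <- parsed$bands
  } else if (is.function(formula)) {
    if (is.null(required_bands)) {
      stop("required_bands must be given when formula is a function")
    }
    fun <- formula
  } else {
    stop("formula must be a function or a formula string")
  }
  assign(key, new_vi_definition(cname, required_bands, fun, reference),
         envir = .vi_registry)
  invisible(cname)
}

#' @rdname register_vi
#' @param path CSV file with columns `name`, `formula` (string form) and
#'   optionally `reference`; each row is registered via [register_vi()].
#' @export
register_vi_config <- function(path, overwrite = FALSE) {
  cfg <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "formula") %in% names(cfg))) {
    stop("VI config must have columns 'name' and 'formula'")
  }
  ref <- if ("reference" %in% names(cfg)) cfg$reference else rep("", nrow(cfg))
  invisible(vapply(seq_len(nrow(cfg)), function(i) {
    register_vi(cfg$name[i], cfg$formula[i], reference = ref[i],
                overwrite = overwrite)
  }, character(1)))
}

#' List registered vegetation indices
#' @return Sorted character vector of canonical VI names.
#' @export
vi_names <- function() {
  sort(vapply(ls(.vi_registry), function(k) .vi_registry[[k]]$name,
              character(1)), method = "radix")
}

#' Look up a registered VI definition
#' @param name Index name (case-insensitive).
#' @return A `vi_definition` (name, required_bands, fun, reference).
#' @export
vi_definition <- function(name) {
  key <- tolower(canonical_vi_name(name))
  if (!key %in% ls(.vi_registry)) {
    stop("unregistered VI '", name, "'; registered: ",
         paste(vi_names(), collapse = ", "))
  }
  .vi_registry[[key]]
}

# ---- safe formula-string parser -------------------------------------------

.vi_symbols <- c(B = "blue", G = "green", R = "red", RE = "rededge",
                 NIR = "nir")
.vi_ops <- c("+", "-", "*", "/", "^", "sqrt", "(")

# Parse an arithmetic expression over {B, G, R, RE, NIR}; only the operators
# + - * / ^ sqrt and numeric literals are admitted, anything else errors.
parse_vi_formula <- function(text) {
  expr <- str2lang(text)
  bands <- character(0)
  walk <- function(e) {
    if (is.numeric(e)) return(invisible())
    if (is.name(e)) {
      s <- as.character(e)
      if (!s %in% names(.vi_symbols)) {
        stop("disallowed symbol '", s, "' in VI formula (allowed: ",
             paste(names(.vi_symbols), collapse = ", "), ")")
      }
      bands <<- union(bands, .vi_symbols[[s]])
      return(invisible())
    }
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (!op %in% .vi_ops) {
        stop("disallowed operator or function '", op, "' in VI formula")
      }
      for (i in seq_along(e)[-1]) walk(e[[i]])
      return(invisible())
    }
    stop("unsupported element in VI formula")
  }
  walk(expr)
  # the closure only reads the bands that appear; absent ones default to 0
  wrapped <- function(bands) {
    b <- unlist(bands)
    get0 <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
    env <- list2env(list(B = get0("blue"), G = get0("green"),
                         R = get0("red"), RE = get0("rededge"),
                         NIR = get0("nir")), parent = baseenv())
    eval(expr, env)
  }
  list(fun = wrapped, bands = bands)
}

# ---- evaluation -----------------------------------------------------------

#' Compute one vegetation index from a band set
#'
#' Evaluates the registered formula after validating the bands it reads.
#' A band combination that makes a denominator zero (or otherwise yields a
#' non-finite value) returns `NA` rather than raising, so the missing value
#' can be carried through correlation screening.
#'
#' @param name Registered VI name (case-insensitive).
#' @param bands Named numeric vector or list with the required bands as
#'   reflectance fractions in [0, 1] (a full [band_set()] always works).
#' @return A single numeric value, or `NA` on a degenerate denominator.
#' @examples
#' compute_vi("NDVI", c(red = 0.1, nir = 0.5))          # 0.6667
#' compute_vi("MTCI", c(red = 0.1, rededge = 0.3, nir = 0.45)) # 0.75
#' compute_vi("MTCI", c(red = 0.3, rededge = 0.3, nir = 0.45)) # NA
#' @export
compute_vi <- function(name, bands) {
  def <- vi_definition(name)
  validate_bands(bands, def$required_bands)
  val <- def$fun(bands)
  if (!is.numeric(val) || length(val) != 1L) {
    stop("VI formula for '", def$name, "' did not return a single number")
  }
  if (!is.finite(val)) return(NA_real_)
  val
}

#' Compute a plots-by-indices VI panel for one flight
#'
#' @param plot_bandsets Named list: plot id -> band set (named vector/list).
#' @param names Character vector of registered VI names.
#' @param flight List or one-row data.frame with `year`, `date`, `dap`,
#'   `stage` describing the flight.
#' @return A `vi_matrix`: numeric matrix (rows = plots, columns = VIs) with
#'   flight metadata attached; missing index values are `NA`.
#' @export
compute_panel <- function(plot_bandsets, names, flight = list()) {
  if (length(plot_bandsets) == 0L) stop("no plots supplied")
  if (length(names) == 0L) stop("no VI names supplied")
  if (is.null(base::names(plot_bandsets))) {
    stop("plot_bandsets must be a named list (plot ids)")
  }
  cnames <- vapply(names, function(n) vi_definition(n)$name, character(1))
  m <- matrix(NA_real_, nrow = length(plot_bandsets), ncol = length(cnames),
              dimnames = list(base::names(plot_bandsets), unname(cnames)))
  for (i in seq_along(plot_bandsets)) {
    for (j in seq_along(cnames)) {
      m[i, j] <- compute_vi(cnames[j], plot_bandsets[[i]])
    }
  }
  new_vi_matrix(m, flight)
}

new_vi_matrix <- function(m, flight = list()) {
  structure(m,
            year = flight$year %||% NA,
            date = flight$date %||% NA,
            dap = flight$dap %||% NA,
            stage = flight$stage %||% NA,
            class = c("vi_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vi_matrix <- function(x, ...) {
  cat(sprintf("<vi_matrix> year=%s stage=%s dap=%s: %d plots x %d indices\n",
              attr(x, "year"), attr(x, "stage"), attr(x, "dap"),
              nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE], ...)
  invisible(x)
}

#' Long-form view of a VI matrix
#' @param x A `vi_matrix`.
#' @param ... Unused.
#' @return data.frame with year, date, dap, stage, plot_id, vi_name, value.
#' @export
as.data.frame.vi_matrix <- function(x, ...) {
  data.frame(
    year = rep(attr(x, "year"), length(x)),
    date = rep(attr(x, "date"), length(x)),
    dap = rep(attr(x, "dap"), length(x)),
    stage = rep(attr(x, "stage"), length(x)),
    plot_id = rep(rownames(x), times = ncol(x)),
    vi_name = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x)),
    stringsAsFactors = FALSE
  )
}

#' Serialize VI panels to / from long CSV
#'
#' Long format: year, date, dap, stage, plot_id, vi_name, value; an empty
#' value cell encodes a missing index value.
#'
#' @param panels A `vi_matrix` or list of them.
#' @param path Output / input CSV path.
#' @export
write_vi_matrix <- function(panels, path) {
  if (inherits(panels, "vi_matrix")) panels <- list(panels)
  long <- do.call(rbind, lapply(panels, as.data.frame))
  utils::write.csv(long, path, row.names = FALSE, na = "")
}

#' @rdname write_vi_matrix
#' @return `read_vi_matrix()` returns a list of `vi_matrix`, one per
#'   (year, date) flight in the file.
#' @export
read_vi_matrix <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(plot_id = "character"))
  long$value <- as.numeric(long$value)
  keys <- unique(long[c("year", "date", "dap", "stage")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- long[long$year == keys$year[i] &
                  long$date == keys$date[i], , drop = FALSE]
    plots <- unique(sub$plot_id)
    vis <- unique(sub$vi_name)
    m <- matrix(NA_real_, length(plots), length(vis),
                dimnames = list(plots, vis))
    m[cbind(match(sub$plot_id, plots), match(sub$vi_name, vis))] <- sub$value
    new_vi_matrix(m, as.list(keys[i, ]))
  })
}

# ---- built-in library -----------------------------------------------------

# Registered at load; forms follow the canonical published definitions with
# narrowband wavelengths resolved through the fixed sensor-band mapping.
register_builtin_vis <- function() {
  reg <- function(name, formula, bands = NULL, ref = "") {
    register_vi(name, formula, required_bands = bands, reference = ref,
                overwrite = TRUE)
  }
  reg("NDVI", "(NIR - R) / (NIR + R)", ref = "normalized difference")
  reg("GNDVI", "(NIR - G) / (NIR + G)", ref = "green normalized difference")
  reg("reNDVI", "(NIR - RE) / (NIR + RE)", ref = "red-edge NDVI")
  reg("SR705", "NIR / RE", ref = "simple ratio 750/705")
  reg("MTCI", "(NIR - RE) / (RE - R)", ref = "MERIS terrestrial chlorophyll")
  reg("LCI", "(NIR - RE) / (NIR + R)", ref = "leaf chlorophyll index")
  reg("RIrededge", "NIR / RE - 1", ref = "red-edge chlorophyll reflectance")
  reg("RIgreen", "NIR / G - 1", ref = "green chlorophyll reflectance")
  reg("CIgreen", "NIR / G - 1", ref = "green chlorophyll index")
  reg("CVI", "NIR * R / (G ^ 2)", ref = "chlorophyll vegetation index")
  reg("mND705", "(NIR - RE) / (NIR + RE - 2 * B)",
      ref = "modified normalized difference 705 (445 nm -> blue)")
  reg("mSR705", "(NIR - B) / (RE - B)",
      ref = "modified simple ratio 705 (445 nm -> blue)")
  reg("DATT", "(NIR - RE) / (NIR - R)", ref = "Datt chlorophyll index")
  reg("SAVI", "1.5 * (NIR - R) / (NIR + R + 0.5)", ref = "soil adjusted, L=0.5")
  reg("OSAVI", "(NIR - R) / (NIR + R + 0.16)", ref = "optimized SAVI")
  reg("MSAVI",
      "0.5 * (2 * NIR + 1 - sqrt((2 * NIR + 1) ^ 2 - 8 * (NIR - R)))",
      ref = "modified SAVI")
  reg("RDVI", "(NIR - R) / sqrt(NIR + R)", ref = "renormalized difference")
  reg("EVI", "2.5 * (NIR - R) / (NIR + 6 * R - 7.5 * B + 1)",
      ref = "enhanced vegetation index")
  reg("WDRVI", "(0.2 * NIR - R) / (0.2 * NIR + R)",
      ref = "wide dynamic range, alpha=0.2")
  reg("VARI", "(G - R) / (G + R - B)", ref = "visible atmospherically resistant")
  reg("TGI", "-0.5 * ((668 - 475) * (R - G) - (668 - 560) * (R - B))",
      ref = "triangular greenness index")
  reg("TVI", "0.5 * (120 * (NIR - G) - 200 * (R - G))",
      ref = "triangular vegetation index")
  reg("MCARI2",
      paste("1.5 * (2.5 * (NIR - R) - 1.3 * (NIR - G)) /",
            "sqrt((2 * NIR + 1) ^ 2 - (6 * NIR - 5 * sqrt(R)) - 0.5)"),
      ref = "modified chlorophyll absorption ratio 2")
  reg("TCARI/OSAVI",
      paste("(3 * ((RE - R) - 0.2 * (RE - G) * (RE / R))) /",
            "((NIR - R) / (NIR + R + 0.16))"),
      ref = "TCARI normalized by OSAVI")
  reg("ARI", "1 / G - 1 / RE", ref = "anthocyanin reflectance index")
  reg("mARI", "NIR * (1 / G - 1 / RE)", ref = "modified ARI")
  reg("CRIrededge", "1 / B - 1 / RE", ref = "carotenoid reflectance, red edge")
  reg("RVI", "NIR / R", ref = "ratio vegetation index")
  reg("SR445", "NIR / B", ref = "simple ratio 800/445 (445 nm -> blue)")
  reg("PBI", "NIR / G", ref = "plant biochemical index 810/560")
  reg("MCARI",
      "((RE - R) - 0.2 * (RE - G)) * (RE / R)",
      ref = "chlorophyll absorption ratio (700 nm -> red edge)")
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_vis()
}
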