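#' @name flucsel-accessors
#' @title Accessors for flucsel classes
#' @description Accessor generics for [HapMatrix-class],
#'   [SeasonalTrajectory-class] and [WilksLDA-class] objects.
#' @param x a flucsel object.
#' @return The slot contents; see the individual methods.
NULL

#' @rdname flucsel-accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname flucsel-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname flucsel-accessors
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))
#' @rdname flucsel-accessors
#' @export
setGeneric("siteClasses", function(x) standardGeneric("siteClasses"))
#' @rdname flucsel-accessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))
#' @rdname flucsel-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname flucsel-accessors
#' @export
setGeneric("derivedFreqs", function(x) standardGeneric("derivedFreqs"))
#' @rdname flucsel-accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname flucsel-accessors
#' @export
setGeneric("seasonLength", function(x) standardGeneric("seasonLength"))
#' @rdname flucsel-accessors
#' @export
setGeneric("restartCount", function(x) standardGeneric("restartCount"))
#' @rdname flucsel-accessors
#' @export
setGeneric("terminalState", function(x) standardGeneric("terminalState"))
#' @rdname flucsel-accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname flucsel-accessors
#' @export
setGeneric("selectionTrace", function(x) standardGeneric("selectionTrace"))

#' @rdname flucsel-accessors
#' @export
setMethod("haplotypes", "HapMatrix", function(x) x@mat)
#' @rdname flucsel-accessors
#' @export
setMethod("positions", "HapMatrix", function(x) x@positions)
#' @rdname flucsel-accessors
#' @export
setMethod("seqLength", "HapMatrix", function(x) x@seqLength)
#' @rdname flucsel-accessors
#' @export
setMethod("siteClasses", "HapMatrix", function(x) x@siteClass)
#' @rdname flucsel-accessors
#' @export
setMethod("nHaplotypes", "HapMatrix", function(x) nrow(x@mat))
#' @rdname flucsel-accessors
#' @export
setMethod("nSites", "HapMatrix", function(x) ncol(x@mat))
#' @rdname flucsel-accessors
#' @export
setMethod("derivedFreqs", "HapMatrix", function(x) {
  if (!ncol(x@mat)) return(numeric())
  colMeans(x@mat)
})

#' @rdname flucsel-accessors
#' @export
setMethod("frequencies", "SeasonalTrajectory", function(x) x@freq)
#' @rdname flucsel-accessors
#' @export
setMethod("seasonLength", "SeasonalTrajectory", function(x) x@seasonLength)
#' @rdname flucsel-accessors
#' @export
setMethod("restartCount", "SeasonalTrajectory", function(x) x@restartCount)
#' @rdname flucsel-accessors
#' @export
setMethod("terminalState", "SeasonalTrajectory", function(x) x@terminalState)

#' @rdname flucsel-accessors
#' @export
setMethod("selectedFeatures", "WilksLDA", function(x) x@features)
#' @rdname flucsel-accessors
#' @export
setMethod("selectionTrace", "WilksLDA", function(x) x@trace)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@mode, "\n")
  cat("  N =", object@N, " L =", format(object@L, big.mark = ","),
      "bp  mu =", object@mu, " r =", object@r, "\n")
  cat("  seasons of", object@g, "generations;", object@nGenerations,
      "selection generations after", object@burnIn, "burn-in\n")
  if (object@mode %in% c("fluctuating"))
    cat("  s_s =", object@sSummer, " s_w =", object@sWinter,
        " h_s =", object@hSummer, " h_w =", object@hWinter, "\n")
  else if (object@mode != "neutral")
    cat("  s =", object@sSummer, " h =", object@hSummer, "\n")
  invisible(NULL)
})

setMethod("show", "HapMatrix", function(object) {
  cat("HapMatrix:", nrow(object@mat), "haplotypes x", ncol(object@mat),
      "segregating sites on", format(object@seqLength, big.mark = ","), "bp\n")
  md <- object@metadata
  if (length(md))
    cat("  metadata:", paste(names(md), unlist(lapply(md, format)),
                             sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "SeasonalTrajectory", function(object) {
  n <- length(object@freq) - 1L
  cat("SeasonalTrajectory (", object@mode, "): ", n, " generations, g = ",
      object@seasonLength, "\n", sep = "")
  cat("  terminal:", object@terminalState, " restarts:", object@restartCount,
      " final frequency:", signif(object@freq[n + 1L], 4), "\n")
  invisible(NULL)
})

setMethod("show", "WilksLDA", function(object) {
  cat("WilksLDA:", length(object@classes), "classes,",
      length(object@features), "selected features\n")
  cat("  path:", paste(object@features, collapse = " -> "), "\n")
  if (nrow(object@trace))
    cat("  final Wilks lambda:",
        signif(object@trace$lambda[nrow(object@trace)], 4), "\n")
  invisible(NULL)
})
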