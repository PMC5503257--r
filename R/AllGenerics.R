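#' @rdname projectVolume
#' @export
setGeneric("projectVolume", function(volume, views, policy = NULL, ...)
  standardGeneric("projectVolume"))

#' @rdname backprojectStack
#' @export
setGeneric("backprojectStack",
           function(stack, geometry = NULL, policy = backprojectionPolicy(),
                    ...)
  standardGeneric("backprojectStack"))

#' @rdname accessors
#' @export
setGeneric("nViews", function(x) standardGeneric("nViews"))

#' @rdname accessors
#' @export
setGeneric("viewAngles", function(x) standardGeneric("viewAngles"))

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname accessors
#' @export
setGeneric("projectionData", function(x) standardGeneric("projectionData"))
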