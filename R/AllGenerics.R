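#' @include utils.R
NULL

#' Accessor generics for rehabsense containers
#'
#' Small accessor layer over the S4 containers: slot access from user code is
#' discouraged, use these instead.
#'
#' @param x A rehabsense S4 object.
#' @return The corresponding component (see the class documentation).
#' @name rehabsense-accessors
NULL

#' @rdname rehabsense-accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname rehabsense-accessors
#' @export
setGeneric("dayIndex", function(x) standardGeneric("dayIndex"))

#' @rdname rehabsense-accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname rehabsense-accessors
#' @export
setGeneric("wearMask", function(x) standardGeneric("wearMask"))

#' @rdname rehabsense-accessors
#' @export
setGeneric("beaconEvents", function(x) standardGeneric("beaconEvents"))

#' @rdname rehabsense-accessors
#' @export
setGeneric("beaconTable", function(x) standardGeneric("beaconTable"))

#' @rdname rehabsense-accessors
#' @export
setGeneric("roomOf", function(x) standardGeneric("roomOf"))

#' @rdname rehabsense-accessors
#' @export
setGeneric("cohortMetadata", function(x) standardGeneric("cohortMetadata"))

#' @rdname rehabsense-accessors
#' @export
setGeneric("accelStreams", function(x) standardGeneric("accelStreams"))

#' @rdname rehabsense-accessors
#' @export
setGeneric("beaconStreams", function(x) standardGeneric("beaconStreams"))

#' @rdname rehabsense-accessors
#' @export
setGeneric("schedules", function(x) standardGeneric("schedules"))
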