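Package: humrep
Title: Robotic Replication of Humeral Motion and Bone-Implant Interface Loads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Maps skin-marker motion-capture trajectories of the humerus into
    feasible joint-space trajectories of a 6-DOF serial industrial robot,
    emits and simulates robot motion programs, verifies achieved kinematics
    against desired kinematics with span-normalized error metrics, and
    computes bone-implant interface loads at the 25% transhumeral amputation
    level via inverse dynamics of a cylinder-segment prosthesis model.
    Includes homogeneous-transform algebra, a configurable serial-manipulator
    model (forward/inverse kinematics, Jacobian, limit checking), optical
    tracker to robot frame identification, gravity-consistent trajectory
    mapping by derivative-free and gradient-based optimization, pose-aware
    non-uniform subsampling, a virtual robot controller, and synthetic
    activity generators for jumping jack, jogging, jug lift, and internal
    rotation archetypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    nloptr,
    signal,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
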