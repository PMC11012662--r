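# Intra-observer (test-retest, round 1 vs round 2) ICC of each of the 12
# observers for each of the ten asymmetry parameters in the original
# validation study. The published per-measure aggregation (mean, SD,
# min, max) and its Total Mean row are recomputed from this matrix.
rater_id,SHA,AHA,WHA,LWA,RWA,WAD,SA,WA,PA,TA
Obsv1,0.946,0.985,0.955,0.977,0.99,0.988,0.927,0.977,0.98,0.969
Obsv2,0.953,0.978,0.926,0.918,0.934,0.997,0.962,0.972,0.994,0.988
Obsv3,0.752,0.791,0.734,0.946,0.887,0.968,0.785,0.899,0.931,0.86
Obsv4,0.992,0.99,0.637,0.99,0.988,0.997,0.966,0.979,0.989,0.98
Obsv5,0.908,0.954,0.943,0.98,0.815,0.947,0.966,0.957,0.961,0.959
Obsv6,0.96,0.975,0.926,0.963,0.979,0.98,0.934,0.98,0.865,0.986
Obsv7,0.931,0.973,0.881,0.973,0.974,0.994,0.901,0.957,0.984,0.971
Obsv8,0.962,0.974,0.985,0.983,0.98,0.99,0.879,0.945,0.989,0.952
Obsv9,0.962,0.985,0.987,0.986,0.941,0.994,0.937,0.978,0.991,0.976
Obsv10,0.993,0.989,0.982,0.993,0.997,0.996,0.941,0.975,0.994,0.975
Obsv11,0.921,0.818,0.655,0.923,0.609,0.931,0.894,0.92,0.946,0.951
Obsv12,0.913,0.966,0.535,0.778,0.796,0.916,0.919,0.974,0.969,0.973
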