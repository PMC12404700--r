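synthetic_movebank_sample.csv
  Two SYNTHETIC individual-nights in the Movebank-style dialect the package
  reads (timestamp, location-long, location-lat,
  individual-local-identifier, fix-status).  Generated with the package's
  own simulator (fixed seeds); it stands in for deposited tracking data in
  format-ingestion tests and examples.  It is not field data.
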