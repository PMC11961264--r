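>HA3_synthetic triple-HA stand-in: three tandem canonical HA epitopes (linkers of the distributed plasmids unknown)
YPYDVPDYAYPYDVPDYAYPYDVPDYA
>HA10_synthetic deca-HA stand-in: ten tandem canonical HA epitopes (linkers of the distributed plasmids unknown)
YPYDVPDYAYPYDVPDYAYPYDVPDYAYPYDVPDYAYPYDVPDYAYPYDVPDYAYPYDVPDYAYPYDVPDYAYPYDVPDYAYPYDVPDYA
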