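# Anterior descent to the expert para-aortic node at world (27, 35, 0) mm
# in the default phantom.
select
move_needle 27 -100 0 0 1 0
scan
move_needle 27 -40 0 0 1 0
scan
move_needle 27 0 0 0 1 0
scan
move_needle 27 35 0 0 1 0
scan
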