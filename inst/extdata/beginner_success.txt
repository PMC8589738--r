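# Straight vertical (anterior) descent to the beginner pararenal node at
# world (70, 20, 0) mm in the default phantom; a scan follows each advance.
select
move_needle 70 -100 0 0 1 0
scan
move_needle 70 -60 0 0 1 0
scan
move_needle 70 -20 0 0 1 0
scan
move_needle 70 0 0 0 1 0
scan
move_needle 70 20 0 0 1 0
scan
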