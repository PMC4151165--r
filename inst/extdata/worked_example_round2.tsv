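t	actor	action	target	status	original_target
34	G	enter_gallery		replayed	
34.5	G	request_up		replayed	
35	G	enter_elevator		replayed	
36	P1	push_up		replayed	
36.1	P	push_alarm		injected	
42	G	exit_elevator		retargeted	
42.5	G	shoot	V6	retargeted	V1
43	G	shoot_participant	P	retargeted	V2
43.5	P1	push_alarm		replayed	
43.5	G	shoot	V3	omitted	
44	G	shoot	V4	omitted	
44.5	G	shoot	V5	omitted	
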