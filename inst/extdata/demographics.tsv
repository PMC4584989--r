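category	level	n	pct_printed
gender	male	33	82.5
gender	female	7	17.5
age_group	21-25	22	55
age_group	26-30	11	27.5
age_group	31-35	7	17.5
education	high_school_diploma	11	27.5
education	some_college_university	27	67.5
education	university_degree	2	5
hormonal_contraceptive	yes	4	10
life_stress	yes	5	12.5
video_game_hours_per_week	under_3	16	40.0
video_game_hours_per_week	3-9	15	37.5
video_game_hours_per_week	10-16	7	17.5
video_game_hours_per_week	17_or_more	2	5.0
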