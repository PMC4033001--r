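"item","subscale"
1,"depression_anxiety"
2,"depression_anxiety"
3,"depression_anxiety"
4,"depression_anxiety"
5,"depression_anxiety"
6,"depression_anxiety"
7,"depression_anxiety"
8,"depression_anxiety"
9,"depression_anxiety"
10,"depression_anxiety"
11,"depression_anxiety"
12,"depression_anxiety"
13,"depression_anxiety"
14,"depression_anxiety"
15,"fatigue"
16,"fatigue"
17,"fatigue"
18,"fatigue"
19,"fatigue"
20,"fatigue"
21,"fatigue"
22,"vigor"
23,"vigor"
24,"vigor"
25,"vigor"
26,"vigor"
27,"vigor"
28,"vigor"
29,"hostility"
30,"hostility"
31,"hostility"
32,"hostility"
33,"hostility"
34,"hostility"
35,"hostility"
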