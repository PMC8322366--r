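study_id,variable,level,n
A,os,android,0
A,os,ios,16
B,os,android,7
B,os,ios,4
C,os,android,12
C,os,ios,0
D,os,android,40
D,os,ios,19
E,os,android,35
E,os,ios,4
F,os,android,69
F,os,ios,5
A,gender,male,4
A,gender,female,12
A,gender,missing,0
B,gender,male,8
B,gender,female,3
B,gender,missing,0
C,gender,male,5
C,gender,female,7
C,gender,missing,0
D,gender,male,0
D,gender,female,57
D,gender,missing,2
E,gender,male,16
E,gender,female,23
E,gender,missing,0
F,gender,male,36
F,gender,female,38
F,gender,missing,0
A,education,high_school,16
A,education,associates,0
A,education,bachelors,0
A,education,graduate,0
A,education,missing,0
B,education,high_school,1
B,education,associates,6
B,education,bachelors,3
B,education,graduate,1
B,education,missing,0
C,education,high_school,12
C,education,associates,0
C,education,bachelors,0
C,education,graduate,0
C,education,missing,0
D,education,high_school,0
D,education,associates,3
D,education,bachelors,36
D,education,graduate,13
D,education,missing,7
E,education,high_school,39
E,education,associates,0
E,education,bachelors,0
E,education,graduate,0
E,education,missing,0
F,education,high_school,74
F,education,associates,0
F,education,bachelors,0
F,education,graduate,0
F,education,missing,0
A,race_ethnicity,non_hispanic_white,7
A,race_ethnicity,non_hispanic_black,4
A,race_ethnicity,asian,5
A,race_ethnicity,american_indian,0
A,race_ethnicity,other_hispanic,0
A,race_ethnicity,missing,0
B,race_ethnicity,non_hispanic_white,9
B,race_ethnicity,non_hispanic_black,1
B,race_ethnicity,asian,1
B,race_ethnicity,american_indian,0
B,race_ethnicity,other_hispanic,0
B,race_ethnicity,missing,0
C,race_ethnicity,non_hispanic_white,9
C,race_ethnicity,non_hispanic_black,2
C,race_ethnicity,asian,1
C,race_ethnicity,american_indian,0
C,race_ethnicity,other_hispanic,0
C,race_ethnicity,missing,0
D,race_ethnicity,non_hispanic_white,32
D,race_ethnicity,non_hispanic_black,12
D,race_ethnicity,asian,7
D,race_ethnicity,american_indian,0
D,race_ethnicity,other_hispanic,5
D,race_ethnicity,missing,3
E,race_ethnicity,non_hispanic_white,14
E,race_ethnicity,non_hispanic_black,3
E,race_ethnicity,asian,14
E,race_ethnicity,american_indian,0
E,race_ethnicity,other_hispanic,5
E,race_ethnicity,missing,3
F,race_ethnicity,non_hispanic_white,46
F,race_ethnicity,non_hispanic_black,9
F,race_ethnicity,asian,9
F,race_ethnicity,american_indian,2
F,race_ethnicity,other_hispanic,5
F,race_ethnicity,missing,3
A,age_mean,mean,19.4
B,age_mean,mean,31.5
C,age_mean,mean,20.4
D,age_mean,mean,41.1
E,age_mean,mean,18.4
F,age_mean,mean,18.2
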