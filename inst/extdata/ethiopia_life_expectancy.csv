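# Published modeled life expectancy at birth (years) for Ethiopian
# population groups, 2000 and 2011. rank: 1 = worst-off in the grouping.
grouping,year,group,rank,pop_share,le
quintile,2011,Lowest,1,0.2,53.4
quintile,2011,Second,2,0.2,56.2
quintile,2011,Middle,3,0.2,60.6
quintile,2011,Fourth,4,0.2,59.9
quintile,2011,Highest,5,0.2,62.5
gender,2000,Male,1,0.5,48.9
gender,2000,Female,2,0.5,50.6
gender,2011,Male,1,0.5,56.7
gender,2011,Female,2,0.5,59.9
residence,2000,Rural,1,0.853,48.9
residence,2000,Urban,2,0.147,55.1
residence,2011,Rural,1,0.83,57.5
residence,2011,Urban,2,0.17,63.1
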